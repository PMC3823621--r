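make_cor_fixture <- function() {
  sheet <- toy_sheet(c("M0", "M1"), 3)
  x <- c(1, 2, 3, 7, 8, 9)
  mi <- toy_matrix(x, "miR-155", sheet$sample_id, feature_kind = "miRNA")
  mr <- toy_matrix(c(x,                     # identical profile
                     2 * mean(x) - x,       # mirrored around the mean
                     c(5.1, 4.8, 5.3, 5.0, 4.9, 5.2), # noise
                     rep(3, 6)),            # flat
                   c("SAME", "MIRROR", "NOISY", "FLAT"),
                   sheet$sample_id)
  list(sheet = sheet, mi = mi, mr = mr, x = x)
}

test_that("Pearson correlation of gene profiles against a miRNA", {
  fx <- make_cor_fixture()
  cors <- correlate_mirna_genes(fx$mi, fx$mr, fx$sheet, "mmu-miR-155",
                                c("M0", "M1"))
  expect_identical(attr(cors, "mirna_id"), "miR-155")
  expect_equal(cors$r[cors$gene_id == "SAME"], 1, tolerance = 1e-12)
  expect_equal(cors$r[cors$gene_id == "MIRROR"], -1, tolerance = 1e-12)
  expect_identical(unique(cors$n_samples), 6L)
  # degenerate gene: r = 0 with a flag, never NA
  flat <- cors[cors$gene_id == "FLAT", ]
  expect_identical(flat$r, 0)
  expect_true(flat$degenerate)
  # direct formula oracle on the noisy gene
  g <- expr_values(fx$mr)["NOISY", ]
  x <- fx$x
  manual <- sum((x - mean(x)) * (g - mean(g))) /
    sqrt(sum((x - mean(x))^2) * sum((g - mean(g))^2))
  expect_equal(cors$r[cors$gene_id == "NOISY"], manual, tolerance = 1e-12)

  expect_error(correlate_mirna_genes(fx$mi, fx$mr, fx$sheet, "miR-999",
                                     c("M0", "M1")), "absent")
  small <- fx$sheet[1:2, ]
  expect_error(
    correlate_mirna_genes(
      toy_matrix(1:2, "miR-155", small$sample_id, feature_kind = "miRNA"),
      toy_matrix(1:2, "G1", small$sample_id), small, "miR-155", "M0"),
    "Fewer than 3")
})

test_that("candidate filtering applies strict |r| and p thresholds", {
  cors <- tibble::tibble(
    gene_id = paste0("G", 1:5),
    r = c(0.5, 0.51, -0.9, 0.9, -0.51),
    n_samples = 6L, degenerate = FALSE
  )
  de <- tibble::tibble(
    feature_id = paste0("G", 1:5),
    p_value = c(1e-6, 1e-6, 0.01, 1e-6, 1e-5)
  )
  out <- filter_candidates(cors, de, r_threshold = 0.5, p_threshold = 1e-4)
  # G1 fails strict r > 0.5, G3 fails p despite r = -0.9
  expect_identical(out, c("G2", "G4", "G5"))
})

test_that("triple intersection follows plain set arithmetic", {
  db_a <- gene_sets(list("miR-155" = c("B", "C", "D")), role = "targets",
                    source_name = "a")
  db_b <- gene_sets(list("miR-155" = c("C", "B")), role = "targets",
                    source_name = "b")
  expect_identical(intersect_targets(c("A", "B", "C"), db_a, db_b, "miR-155"),
                   c("B", "C"))
  db_c <- gene_sets(list("miR-155" = c("X", "Y")), role = "targets",
                    source_name = "c")
  expect_identical(intersect_targets(c("A", "B"), db_a, db_c, "miR-155"),
                   character(0))
  # both databases lack miR-124, so each contributes a warning
  expect_warning(
    expect_warning(
      out <- intersect_targets(c("A", "B"), db_a, db_b, "miR-124"),
      "absent"
    ),
    "absent"
  )
  expect_identical(out, character(0))
})

test_that("interactome construction and direction classification", {
  cors <- structure(tibble::tibble(
    gene_id = c("UPGENE", "DOWNGENE", "OTHER"),
    r = c(0.9, -0.94, 0.2),
    n_samples = 6L, degenerate = FALSE
  ), mirna_id = "miR-155")
  de <- tibble::tibble(
    feature_id = c("UPGENE", "DOWNGENE", "OTHER"),
    log2_fold_change = c(1.2, -3.370, 0.4),
    p_value = c(1e-6, 7.86e-10, 0.2)
  )
  ia <- build_interactome(c("UPGENE", "DOWNGENE"), cors, de)
  expect_s3_class(ia, "polarmir_interactome")
  expect_identical(ia$direction,
                   c("positively_correlated", "inversely_correlated"))
  down <- ia[ia$gene_symbol == "DOWNGENE", ]
  expect_equal(down$correlation_factor, -0.94)
  expect_equal(down$log2_fold_change, -3.370)
  expect_identical(down$direction, "inversely_correlated")

  expect_error(build_interactome("MISSING", cors, de), "missing")
  empty <- build_interactome(character(0), cors, de)
  expect_identical(nrow(empty), 0L)
  counts <- classify_directions(ia)
  expect_identical(counts$n_positive, 1L)
  expect_identical(counts$n_negative, 1L)
  expect_identical(classify_directions(empty),
                   tibble::tibble(n_positive = 0L, n_negative = 0L))
  # direction counts match a brute-force sign count on a random table
  set.seed(5)
  rnd <- build_interactome(
    paste0("R", 1:30),
    structure(tibble::tibble(gene_id = paste0("R", 1:30),
                             r = runif(30, -1, 1), n_samples = 6L,
                             degenerate = FALSE), mirna_id = "miR-1"),
    tibble::tibble(feature_id = paste0("R", 1:30),
                   log2_fold_change = rnorm(30), p_value = runif(30, 0, 1e-5)))
  cd <- classify_directions(rnd)
  expect_identical(cd$n_negative, sum(rnd$correlation_factor < 0))
  expect_identical(cd$n_positive + cd$n_negative, 30L)
})

test_that("the packaged interactome fixture is coherent and re-sortable", {
  ia <- read_interactome(table2_path())
  expect_identical(nrow(ia), 112L)
  counts <- classify_directions(ia)
  expect_identical(counts$n_positive, 44L)
  expect_identical(counts$n_negative, 68L)
  # direction is determined by the sign of the correlation on every row
  expect_identical(ia$direction == "inversely_correlated",
                   ia$correlation_factor < 0)
  # rebuilding from the fixture's own columns reproduces it (idempotence)
  cors <- structure(tibble::tibble(gene_id = ia$gene_symbol,
                                   r = ia$correlation_factor,
                                   n_samples = 6L, degenerate = FALSE),
                    mirna_id = "miR-155")
  de <- tibble::tibble(feature_id = ia$gene_symbol,
                       log2_fold_change = ia$log2_fold_change,
                       p_value = ia$power)
  rebuilt <- build_interactome(ia$gene_symbol, cors, de,
                               descriptions = stats::setNames(
                                 ia$description, ia$gene_symbol))
  expect_identical(nrow(rebuilt), 112L)
  resorted <- polarmir:::sort_interactome(rebuilt)
  expect_identical(as.data.frame(resorted), as.data.frame(rebuilt))
  # rebuild-of-rebuild is exactly stable
  rebuilt2 <- build_interactome(
    rebuilt$gene_symbol,
    structure(tibble::tibble(gene_id = rebuilt$gene_symbol,
                             r = rebuilt$correlation_factor,
                             n_samples = 6L, degenerate = FALSE),
              mirna_id = "miR-155"),
    tibble::tibble(feature_id = rebuilt$gene_symbol,
                   log2_fold_change = rebuilt$log2_fold_change,
                   p_value = rebuilt$power))
  expect_identical(as.data.frame(rebuilt2[-3]), as.data.frame(rebuilt[-3]))
  # within each class the fixture follows descending |log2FC| order up to
  # one printed rounding inversion in the down class
  per_class <- split(abs(ia$log2_fold_change), ia$direction)
  violations <- sum(diff(per_class$inversely_correlated) > 1e-9) +
    sum(diff(per_class$positively_correlated) > 1e-9)
  expect_lte(violations, 1L)
})

test_that("overlap fractions obey set arithmetic and the triple bound", {
  # candidates subset of both databases -> all fractions 1
  o <- overlap_fractions(c("A", "B"), c("A", "B", "C"), c("A", "B", "D"))
  expect_equal(o$frac_overlap_a, 1)
  expect_equal(o$frac_overlap_b, 1)
  expect_equal(o$frac_triple, 1)
  # the 18% / 6% / 3% style arithmetic
  cands <- sprintf("G%03d", 1:100)
  o2 <- overlap_fractions(cands, cands[1:18], cands[c(1:3, 19:21)])
  expect_equal(o2$frac_overlap_a, 0.18)
  expect_equal(o2$frac_overlap_b, 0.06)
  expect_equal(o2$frac_triple, 0.03)
  # random sets: fractions match brute-force arithmetic and the bound holds
  set.seed(77)
  for (i in 1:20) {
    cand <- sample(cands, sample(5:60, 1))
    a <- sample(cands, sample(5:60, 1))
    b <- sample(cands, sample(5:60, 1))
    o3 <- overlap_fractions(cand, a, b)
    expect_identical(o3$n_triple, length(intersect(intersect(cand, a), b)))
    expect_lte(o3$frac_triple,
               min(o3$frac_overlap_a, o3$frac_overlap_b) + 1e-12)
  }
  expect_warning(o4 <- overlap_fractions(character(0), "A", "B"), "undefined")
  expect_true(o4$degenerate)
  expect_true(is.na(o4$frac_triple))
})

test_that("inverse classification of recovered targets grows with |beta|", {
  frac_inverse <- function(beta) {
    sim <- simulate_microglia(seed = 123, noise_sd = 0.2,
                              beta_repressive = -beta, beta_activating = 0,
                              n_repressive = 8, n_activating = 0,
                              db_sensitivity = 1, db_noise = 0)
    de <- run_contrast(sim$mrna, sim$samples, "M1", "M0")
    cors <- correlate_mirna_genes(sim$mirna, sim$mrna, sim$samples,
                                  "miR-155like", c("M0", "M1"))
    truth <- sim$truth$regulatory_edges
    tg <- truth$gene_id[truth$mirna_id == "miR-155like"]
    # of the true repressed targets recovered at the screen thresholds,
    # how many are classified inversely correlated?
    cand <- filter_candidates(cors, de)
    hit <- intersect(tg, cand)
    if (length(hit) == 0) return(0)
    ia <- build_interactome(hit, cors, de)
    mean(ia$direction == "inversely_correlated")
  }
  fr <- vapply(c(0.05, 0.6, 2), frac_inverse, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[3], 1)
})
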