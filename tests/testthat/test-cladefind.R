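# small fixture: an orthogroup whose truth clade is planted gapless
planted_case <- function(seed = 1, n_proteomes = 6,
                         decoy_proteomes = c("BOVIN", "MONDO"), ...) {
  set.seed(seed)
  cfg <- simulation_config(n_proteomes = n_proteomes, n_orthogroups = 1,
                           seed = seed, ...)
  g <- generate_orthogroup(1, cfg, decoy_proteomes = decoy_proteomes)
  gdm <- gap_distance_matrix(g$msa)
  list(g = g, gdm = gdm, tree = nj_tree(gdm),
       rec = g$bundle$members)
}

test_that("clade cost is the maximum pairwise gap distance, zero iff gapless", {
  pc <- planted_case()
  truth_accs <- pc$g$truth$true_canonical
  expect_equal(clade_cost(truth_accs, pc$gdm), 0)
  all_accs <- pc$rec$accession
  expect_gt(clade_cost(all_accs, pc$gdm), 0.02)
  expect_warning(c0 <- clade_cost(all_accs[1], pc$gdm), "singleton")
  expect_equal(c0, 0)
})

test_that("the 0.02 threshold is inclusive and large one-sided gaps reject", {
  # a pair with a 5-column gap over effective length 250: cost exactly 0.02
  rows <- c(X1 = strrep("M", 250),
            X2 = paste0(strrep("M", 100), strrep("-", 5), strrep("M", 145)),
            X3 = strrep("M", 250))
  gdm <- gap_distance_matrix(rows)
  rec <- make_records(c("X1", "X2", "X3"), c("HUMAN", "MOUSE", "RAT"),
                      residues = gsub("-", "", rows))
  tr <- nj_tree(gdm)
  cands <- find_low_cost_clades(tr, gdm, rec, cost_threshold = 0.02,
                                min_proteomes = 3)
  expect_length(cands, 1)
  expect_equal(cands[[1]]$cost, 0.02)
  # a ~104-column one-sided gap over ~400 columns: cost ~0.26, rejected
  rows2 <- c(Y1 = strrep("M", 400),
             Y2 = paste0(strrep("M", 150), strrep("-", 104),
                         strrep("M", 146)),
             Y3 = strrep("M", 400))
  gdm2 <- gap_distance_matrix(rows2)
  expect_equal(clade_cost(c("Y1", "Y2"), gdm2), 104 / 400)
  rec2 <- make_records(c("Y1", "Y2", "Y3"), c("HUMAN", "MOUSE", "RAT"),
                       residues = gsub("-", "", rows2))
  cands2 <- find_low_cost_clades(nj_tree(gdm2), gdm2, rec2)
  for (cd in cands2) expect_false("Y2" %in% cd$accessions)
})

test_that("a planted gapless clade across six proteomes is the only candidate", {
  pc <- planted_case(seed = 3,
                     decoy_proteomes = c("HUMAN", "MOUSE", "RAT",
                                         "BOVIN", "CANLF", "MONDO"))
  cands <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec,
                                orthogroup_id = "OG")
  expect_length(cands, 1)
  expect_equal(cands[[1]]$n_proteomes, 6L)
  expect_equal(cands[[1]]$cost, 0)
  expect_setequal(cands[[1]]$accessions, pc$g$truth$true_canonical)
})

test_that("clades spanning fewer than min_proteomes proteomes are not emitted", {
  rows <- c(A1 = strrep("M", 20), B1 = strrep("M", 20),
            C1 = paste0(strrep("-", 10), strrep("M", 10)),
            D1 = paste0(strrep("M", 10), strrep("-", 10)))
  gdm <- gap_distance_matrix(rows)
  rec <- make_records(c("A1", "B1", "C1", "D1"),
                      c("HUMAN", "MOUSE", "RAT", "CANLF"),
                      residues = gsub("-", "", rows))
  cands <- find_low_cost_clades(nj_tree(gdm), gdm, rec, min_proteomes = 3)
  expect_length(cands, 0)   # the only low-cost clade spans HUMAN+MOUSE
  cands2 <- find_low_cost_clades(nj_tree(gdm), gdm, rec, min_proteomes = 2)
  expect_length(cands2, 1)
  expect_setequal(cands2[[1]]$accessions, c("A1", "B1"))
})

test_that("no candidate ever holds two sequences from one proteome", {
  set.seed(301)
  for (rep in 1:10) {
    pc <- planted_case(seed = 300 + rep, include_short_isoform = TRUE)
    cands <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec)
    for (cd in cands)
      expect_false(anyDuplicated(cd$members$proteome_id) > 0)
  }
})

test_that("candidates match brute-force subset enumeration at small scale", {
  set.seed(302)
  for (rep in 1:25) {
    pc <- planted_case(seed = 400 + rep,
                       n_proteomes = sample(4:6, 1),
                       decoy_proteomes = NULL,
                       include_short_isoform = sample(c(TRUE, FALSE), 1))
    if (length(pc$rec$accession) > 8) next
    mine <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec)
    oracle <- oracle_candidates(pc$tree, pc$gdm$d, pc$rec)
    expect_identical(candidate_keys(mine), candidate_keys(oracle))
  }
})

test_that("raising the threshold or lowering min_proteomes only grows coverage", {
  set.seed(303)
  for (rep in 1:8) {
    pc <- planted_case(seed = 500 + rep, include_short_isoform = TRUE)
    lo <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec,
                               cost_threshold = 0.02)
    hi <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec,
                               cost_threshold = 0.05)
    # every accepted clade at the stricter threshold survives, possibly
    # absorbed into a larger accepted clade
    for (cd in lo)
      expect_true(any(vapply(hi, function(h)
        all(cd$accessions %in% h$accessions), TRUE)))
    fewer <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec, min_proteomes = 4)
    more <- find_low_cost_clades(pc$tree, pc$gdm, pc$rec, min_proteomes = 3)
    for (cd in fewer)
      expect_true(any(vapply(more, function(h)
        all(cd$accessions %in% h$accessions), TRUE)))
  }
})
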