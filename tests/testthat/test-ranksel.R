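fake_candidate <- function(accs, proteomes, cost = 0, canonical = TRUE,
                           reviewed = FALSE, gene_group = proteomes,
                           lengths = NULL, og = "OG1") {
  rec <- make_records(accs, proteomes, canonical = canonical,
                      reviewed = reviewed, gene_group = gene_group,
                      residues = if (is.null(lengths)) NULL else
                        strrep("M", lengths))
  list(orthogroup_id = og, accessions = sort(accs), members = rec,
       cost = cost, n_proteomes = length(unique(proteomes)),
       n_canonical = sum(rec$is_canonical),
       n_reviewed_hm = sum(rec$review_status == "reviewed" &
                             rec$proteome_id %in% c("HUMAN", "MOUSE")),
       length_deviation = NA_real_, source_node = NA_integer_)
}

test_that("length penalty is the relative deviation of medians", {
  expect_equal(length_penalty(c(196, 196, 196), c(196, 210, 196)), 0)
  expect_equal(length_penalty(256, 196), 60 / 196)
  expect_equal(length_penalty(100, c(150, 200, 400)), 100 / 200)
  expect_warning(p <- length_penalty(c(100, 110), integer(0)), "penalty")
  expect_equal(p, 0)
})

test_that("ranking is strict lexicographic over the five criteria", {
  # criterion (i) cost dominates proteome count
  a <- fake_candidate("A1", "HUMAN", cost = 0)
  a$n_proteomes <- 5L
  b <- fake_candidate("B1", "HUMAN", cost = 0.01)
  b$n_proteomes <- 7L
  rk <- rank_clades(list(b, a), canonical_lengths = 11)
  expect_equal(rk[[1]]$accessions, "A1")
  # (iii) canonical count at equal cost and size
  c3 <- fake_candidate(c("C1", "C2", "C3"), c("HUMAN", "MOUSE", "RAT"),
                       canonical = c(TRUE, TRUE, TRUE))
  c1 <- fake_candidate(c("E1", "E2", "E3"), c("HUMAN", "MOUSE", "RAT"),
                       canonical = c(TRUE, FALSE, FALSE))
  rk2 <- rank_clades(list(c1, c3), canonical_lengths = c(12, 13, 14))
  expect_equal(rk2[[1]]$n_canonical, 3L)
  # (iv) reviewed human/mouse entries break the remaining tie
  r0 <- fake_candidate(c("F1", "F2"), c("RAT", "BOVIN"), reviewed = TRUE)
  r2 <- fake_candidate(c("G1", "G2"), c("HUMAN", "MOUSE"), reviewed = TRUE)
  r0$n_proteomes <- r2$n_proteomes <- 2L
  rk3 <- rank_clades(list(r0, r2), canonical_lengths = c(12, 13))
  expect_equal(rk3[[1]]$n_reviewed_hm, 2L)
  # (v) smaller length deviation wins; then accession for full ties
  s1 <- fake_candidate(c("H1", "H2"), c("HUMAN", "MOUSE"), lengths = 200)
  s2 <- fake_candidate(c("I1", "I2"), c("HUMAN", "MOUSE"), lengths = 100)
  rk4 <- rank_clades(list(s1, s2), canonical_lengths = c(100, 100))
  expect_equal(rk4[[1]]$accessions, c("I1", "I2"))
  t1 <- fake_candidate(c("J1", "J2"), c("HUMAN", "MOUSE"), lengths = 100)
  t2 <- fake_candidate(c("K1", "K2"), c("HUMAN", "MOUSE"), lengths = 100)
  rk5 <- rank_clades(list(t2, t1), canonical_lengths = 100)
  expect_equal(rk5[[1]]$accessions, c("J1", "J2"))
  expect_equal(vapply(rk5, `[[`, 0L, "rank"), 1:2)
})

test_that("selection keeps the best clade per disjoint gene set", {
  # three clades over disjoint gene groups: all selected
  g1 <- fake_candidate(c("A1", "A2", "A3"), c("HUMAN", "MOUSE", "RAT"),
                       gene_group = c("gA.H", "gA.M", "gA.R"))
  g2 <- fake_candidate(c("B1", "B2", "B3"), c("HUMAN", "MOUSE", "RAT"),
                       gene_group = c("gB.H", "gB.M", "gB.R"), cost = 0.01)
  g3 <- fake_candidate(c("C1", "C2", "C3"), c("BOVIN", "CANLF", "MONDO"),
                       gene_group = c("gC.B", "gC.C", "gC.M"), cost = 0.015)
  sel <- select_clades(rank_clades(list(g2, g3, g1), 11:13))
  expect_length(sel, 3)
  # overlapping gene groups: only the better-ranked clade survives
  h2 <- fake_candidate(c("B9", "B2", "B3"), c("GORGO", "MOUSE", "RAT"),
                       gene_group = c("gX.G", "gB.M", "gB.R"), cost = 0.02)
  sel2 <- select_clades(rank_clades(list(g2, h2), 11:13))
  expect_length(sel2, 1)
  expect_equal(sel2[[1]]$cost, 0.01)
  sel3 <- select_clades(rank_clades(list(g1), 11:13))
  expect_length(sel3, 1)
})

test_that("suggestions classify confirm / propose_change / flag_reviewed", {
  # cow's canonical is a longer decoy; a 196-aa isoform sits in the clade
  rec <- seq_records(
    accession = c("HUM1", "MOU1", "COW1", "COWISO-1"),
    proteome_id = c("HUMAN", "MOUSE", "BOVIN", "BOVIN"),
    residues = c(strrep("M", 196), strrep("M", 196), strrep("M", 210),
                 strrep("M", 196)),
    review_status = c("reviewed", "reviewed", "unreviewed", "unreviewed"),
    is_canonical = c(TRUE, TRUE, TRUE, FALSE),
    gene_group_id = c("gH", "gM", "gC", "gC"))
  cand <- list(orthogroup_id = "OG1",
               accessions = c("COWISO-1", "HUM1", "MOU1"),
               members = rec[match(c("HUM1", "MOU1", "COWISO-1"),
                                   rec$accession), ],
               cost = 0, n_proteomes = 3L, n_canonical = 2L,
               n_reviewed_hm = 2L, length_deviation = 0, source_node = 1L,
               rank = 1L)
  sugg <- emit_suggestions(list(cand), rec)
  expect_equal(nrow(sugg), 3)
  expect_setequal(sugg$action[sugg$proteome_id %in% c("HUMAN", "MOUSE")],
                  "confirm")
  cow <- sugg[sugg$proteome_id == "BOVIN", ]
  expect_equal(cow$action, "propose_change")
  expect_equal(cow$old_canonical, "COW1")
  expect_equal(cow$new_canonical, "COWISO")   # base accession
  # same situation but the displaced canonical is reviewed: flag only
  rec2 <- rec
  rec2$review_status[rec2$accession == "COW1"] <- "reviewed"
  cand2 <- cand
  cand2$members <- rec2[match(cand$members$accession, rec2$accession), ]
  sugg2 <- emit_suggestions(list(cand2), rec2)
  expect_equal(sugg2$action[sugg2$proteome_id == "BOVIN"], "flag_reviewed")
  # an all-canonical clade confirms everything
  cand3 <- cand
  cand3$accessions <- c("COW1", "HUM1", "MOU1")
  cand3$members <- rec[match(c("HUM1", "MOU1", "COW1"), rec$accession), ]
  sugg3 <- emit_suggestions(list(cand3), rec)
  expect_setequal(sugg3$action, "confirm")
  expect_equal(sugg3$old_canonical, sugg3$new_canonical)
})

test_that("each gene group yields at most one suggestion per orthogroup", {
  set.seed(601)
  for (rep in 1:5) {
    cfg <- simulation_config(n_proteomes = 6, n_orthogroups = 4,
                             include_short_isoform = TRUE,
                             seed = 600 + rep)
    ds <- generate_dataset(cfg)
    run <- run_pipeline(ds$bundles, msas = ds$msas)
    key <- paste(run$suggestions$orthogroup_id,
                 run$suggestions$gene_group_id)
    expect_false(any(duplicated(key)))
  }
})
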