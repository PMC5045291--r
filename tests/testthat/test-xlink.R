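xl <- function(...) {
  df <- data.frame(...)
  defaults <- list(protein_a = "Cac1", res_a = 10L, protein_b = "Cac2",
                   res_b = 20L, chemistry = "DSS", score = 30, expect = 1e-7)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df
}

test_that("score/expect filter keeps only records passing both thresholds", {
  recs <- rbind(xl(score = 25, expect = 1e-6),   # passes both
                xl(score = 25, expect = 1e-4),   # fails expect
                xl(score = 15, expect = 1e-7),   # fails score
                xl(score = 20, expect = 1e-7))   # boundary: score not > 20
  out <- filter_crosslinks(recs)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_in"), 4)
  expect_equal(attr(out, "n_kept"), 1)
  # empty in, empty out
  expect_equal(nrow(filter_crosslinks(recs[0, ])), 0)
  # subset and idempotence
  again <- filter_crosslinks(out)
  expect_equal(again$score, out$score)
  expect_true(all(out$score %in% recs$score))
})

test_that("linkage map classifies, deduplicates and counts links", {
  lens <- c(Cac1 = 606, Cac2 = 468, Cac3 = 422, H3 = 135, H4 = 102)
  one <- xl(protein_a = "Cac1", res_a = 100L, protein_b = "Cac1", res_b = 200L)
  m1 <- build_linkage_map(one, lens)
  expect_equal(m1$n_intra, 1); expect_equal(m1$n_inter, 0)
  expect_equal(m1$links$multiplicity, 1L)
  # same pair twice (either orientation) collapses with multiplicity 2
  two <- rbind(one, xl(protein_a = "Cac1", res_a = 200L,
                       protein_b = "Cac1", res_b = 100L))
  m2 <- build_linkage_map(two, lens)
  expect_equal(nrow(m2$links), 1)
  expect_equal(m2$links$multiplicity, 2L)
  # mixed intra/inter enumeration
  mix <- rbind(
    xl(protein_a = "Cac1", res_a = 10L, protein_b = "Cac1", res_b = 60L),
    xl(protein_a = "Cac1", res_a = 118L, protein_b = "Cac1", res_b = 334L),
    xl(protein_a = "Cac2", res_a = 5L, protein_b = "Cac2", res_b = 90L),
    xl(protein_a = "Cac1", res_a = 577L, protein_b = "H3", res_b = 64L),
    xl(protein_a = "Cac1", res_a = 444L, protein_b = "H3", res_b = 59L,
       chemistry = "EDC"))
  m3 <- build_linkage_map(mix, lens)
  expect_equal(m3$n_intra, 3); expect_equal(m3$n_inter, 2)
  expect_error(build_linkage_map(xl(res_a = 700L), lens), "beyond protein length")
  expect_error(build_linkage_map(one, lens[-1]), "no length")
})

test_that("structure validation measures CA-CA distances and flags unmapped links", {
  model <- structure_model(data.frame(
    chain = "A", resno = c(10L, 20L, 30L), resname = "ALA", atom_name = "CA",
    element = "C", x = c(0, 10, 40), y = 0, z = 0))
  mapping <- list(Cac1 = c(chain = "A", offset = 0))
  recs <- rbind(
    xl(protein_a = "Cac1", res_a = 10L, protein_b = "Cac1", res_b = 10L),
    xl(protein_a = "Cac1", res_a = 10L, protein_b = "Cac1", res_b = 20L),
    xl(protein_a = "Cac1", res_a = 10L, protein_b = "Cac1", res_b = 30L),
    xl(protein_a = "Cac1", res_a = 10L, protein_b = "Cac1", res_b = 578L))
  out <- suppressWarnings(
    validate_against_structure(recs, model, mapping))
  expect_equal(out$per_link$distance[1:3], c(0, 10, 40))
  expect_equal(out$per_link$satisfied[1:3], c(TRUE, TRUE, FALSE))
  # residue absent from the structure (disordered segment)
  expect_false(out$per_link$mapped[4])
  expect_equal(unname(out$summary["DSS"]), 2 / 3)
  # tighter threshold flips the 10 A link
  out8 <- suppressWarnings(
    validate_against_structure(recs[2, ], model, mapping,
                               thresholds = c(DSS = 8, EDC = 16)))
  expect_false(out8$per_link$satisfied)
})

test_that("validation distances are symmetric and rigid-motion invariant", {
  m <- synthetic_ca_model(40, seed = 51)
  mapping <- list(Cac1 = c(chain = "A", offset = 0))
  recs <- xl(protein_a = "Cac1", res_a = 3L, protein_b = "Cac1", res_b = 30L)
  swapped <- xl(protein_a = "Cac1", res_a = 30L, protein_b = "Cac1", res_b = 3L)
  d1 <- validate_against_structure(recs, m, mapping)$per_link$distance
  d2 <- validate_against_structure(swapped, m, mapping)$per_link$distance
  expect_equal(d1, d2)
  set.seed(52)
  moved <- apply_transform(m, rigid_transform(random_rotation(), rnorm(3, 0, 20)))
  d3 <- validate_against_structure(recs, moved, mapping)$per_link$distance
  expect_equal(d1, d3, tolerance = 1e-9)
})

test_that("synthetic true/decoy links are separated exactly by filter and structure", {
  m <- synthetic_ca_model(80, seed = 53)
  recs <- gen_xlinks(m, n_true = 12, n_decoy = 8, seed = 54)
  kept <- filter_crosslinks(recs)
  expect_equal(nrow(kept), 12)
  expect_true(all(kept$is_true))
  val <- validate_against_structure(recs, m,
                                    list(Cac1 = c(chain = "A", offset = 0)))
  expect_equal(val$per_link$satisfied, recs$is_true)
})

test_that("sequence mass: frozen oracle values, additivity, errors", {
  # frozen against an independent proteomics mass calculator
  expect_equal(sequence_mass("GG"), 132.118, tolerance = 0.01)
  expect_equal(sequence_mass("PEPTIDE", "monoisotopic"), 799.3600,
               tolerance = 1e-3)
  expect_equal(sequence_mass("ACDEFGHIKLMNPQRSTVWY", "monoisotopic"),
               2394.1249, tolerance = 1e-3)
  expect_equal(sequence_mass("ACDEFGHIKLMNPQRSTVWY"), 2395.717,
               tolerance = 0.05)
  # peptide-bond additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(55)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
  for (i in 1:10) {
    s1 <- paste(sample(aa, 6, TRUE), collapse = "")
    s2 <- paste(sample(aa, 9, TRUE), collapse = "")
    expect_equal(sequence_mass(paste0(s1, s2)),
                 sequence_mass(s1) + sequence_mass(s2) - 18.01528,
                 tolerance = 1e-9)
  }
  expect_error(sequence_mass(""), "empty")
  expect_error(sequence_mass("AXZ"), "unknown residue")
})
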