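test_that("QC rates are computed on the right denominators", {
  set.seed(4)
  n <- 200
  calls <- rbind(
    # 19 of 200 missing: missing rate 0.095
    mostlyMissing = c(rep(NA_character_, 19), rep("GG", 181)),
    allHom1 = rep("AA", n),
    halfHalf = c(rep("CC", 100), rep("TT", 100)),
    # 10 het among 100 non-missing: het rate 0.10, MAF over 90 homs
    hetMix = c(rep(NA, 100), rep("GT", 10), rep("GG", 60), rep("TT", 30)))
  colnames(calls) <- sprintf("cv%03d", 1:n)
  info <- markerInfo(qcStats(MarkerPanel(calls)))
  expect_equal(info$missing_rate,
               c(19 / 200, 0, 0, 100 / 200))
  expect_equal(info$het_rate, c(0, 0, 0, 10 / 100))
  expect_equal(info$maf, c(0, 0, 0.5, 30 / 90))
  expect_equal(info$n_hom, c(181L, 200L, 200L, 90L))
  # no calls at all: rates defined, MAF flagged undefined
  empty <- MarkerPanel(rbind(void = rep(NA_character_, 4)) |>
                         `colnames<-`(paste0("g", 1:4)))
  i2 <- markerInfo(qcStats(empty))
  expect_equal(i2$missing_rate, 1)
  expect_true(is.na(i2$maf))
})

test_that("the filter cascade reproduces the constructed 38-marker composition", {
  sim <- simulatePanel(simulationConfig(), seed = 23)
  panel <- applyFilters(qcStats(harmonizeStrand(sim$panel)))
  info <- markerInfo(panel)
  expect_equal(nrow(info), 38)
  expect_equal(sum(info$status == "retained"), 22)
  expect_equal(as.vector(table(info$reason)[c(
    "high_missing", "high_het", "monomorphic", "low_maf")]),
    c(6L, 2L, 7L, 1L))
  expect_length(retainedMarkers(panel), 22)
  # bookkeeping: input = retained + per-reason exclusions
  expect_equal(nrow(info),
               sum(info$status == "retained") +
                 sum(info$reason != "none"))
  # idempotence: filtering the retained subset excludes nothing further
  again <- applyFilters(qcStats(panel[retainedMarkers(panel), ]))
  expect_true(all(markerInfo(again)$status == "retained"))
})

test_that("cascade order gives one primary reason per exclusion", {
  n <- 40
  calls <- rbind(
    bothBad = c(rep(NA, 20), rep("GT", 10), rep("GG", 10)),  # 50% missing AND 50% het
    hetMono = c(rep("AC", 10), rep("AA", 30)),               # high het, then mono
    clean = c(rep("TT", 20), rep("CC", 20)))
  colnames(calls) <- paste0("g", 1:n)
  info <- markerInfo(applyFilters(qcStats(MarkerPanel(calls))))
  expect_equal(info$reason, c("high_missing", "high_het", "none"))
  # all-clean matrix: nothing excluded
  expect_equal(sum(info$status == "excluded"), 2)
})

test_that("dropping heterozygotes conserves counts", {
  calls <- rbind(m1 = c("GT", "GT", "GT", "GT"),
                 m2 = c("AA", "AA", "CC", "CC"),
                 m3 = c("AG", NA, "AA", "GG"))
  colnames(calls) <- paste0("g", 1:4)
  panel <- MarkerPanel(calls)
  before <- markerCalls(panel)
  dropped <- markerCalls(dropHeterozygotes(panel))
  expect_true(all(is.na(dropped["m1", ])))
  expect_equal(dropped["m2", ], before["m2", ])
  expect_equal(sum(is.na(dropped)),
               sum(is.na(before)) + sum(before %in% c("GT", "AG")))
})

test_that("strand harmonization complements flagged markers and is an involution", {
  calls <- rbind(flagged = c("GG", "TT", "GT"),
                 plain = c("AA", "CC", "AC"))
  colnames(calls) <- paste0("g", 1:3)
  meta <- data.frame(marker_id = c("flagged", "plain"),
                     allele1 = c("G", "A"), allele2 = c("T", "C"),
                     strand_flag = c(TRUE, FALSE),
                     tolerant_allele = c("G", NA))
  panel <- MarkerPanel(calls, meta)
  h <- harmonizeStrand(panel)
  expect_equal(unname(markerCalls(h)["flagged", ]), c("CC", "AA", "CA"))
  expect_equal(unname(markerCalls(h)["plain", ]), c("AA", "CC", "AC"))
  info <- markerInfo(h)
  expect_equal(info$allele1[1], "C")
  expect_equal(info$tolerant_allele[1], "C")
  # involution: applying twice restores the original panel
  twice <- harmonizeStrand(h)
  expect_identical(markerCalls(twice), markerCalls(panel))
  expect_identical(markerInfo(twice), markerInfo(panel))
  # non-nucleotide alleles cannot be complemented
  indel <- MarkerPanel(rbind(ins = c("II", "DD", "ID")) |>
                         `colnames<-`(paste0("g", 1:3)),
                       data.frame(marker_id = "ins", allele1 = "I",
                                  allele2 = "D", strand_flag = TRUE))
  expect_error(harmonizeStrand(indel), "non-nucleotide")
})

test_that("complete-LD detection groups identical partitions only", {
  calls <- rbind(
    a = c("GG", "GG", "TT", "TT", "GG", "TT"),
    b = c("AA", "AA", "CC", "CC", "AA", "CC"),   # same partition, relabeled
    c = c("GG", "GG", "TT", "TT", "TT", "TT"),   # one genotype discordant
    d = c("AA", "CC", "AA", "CC", "AA", "CC"))   # unrelated
  colnames(calls) <- paste0("g", 1:6)
  groups <- detectCompleteLD(MarkerPanel(calls))
  expect_length(groups, 1)
  expect_setequal(groups[[1]]$markers, c("a", "b"))
  expect_equal(groups[[1]]$representative, "a")
  # missing cells are handled pairwise; monomorphic-over-shared is no match
  calls2 <- rbind(a = c("GG", "GG", NA, "TT"),
                  b = c("AA", "AA", "CC", NA))
  colnames(calls2) <- paste0("g", 1:4)
  expect_length(detectCompleteLD(MarkerPanel(calls2)), 0)
  # the default synthetic panel carries exactly the two planted LD pairs
  sim <- simulatePanel(simulationConfig(), seed = 31)
  panel <- dropHeterozygotes(applyFilters(qcStats(
    harmonizeStrand(sim$panel))))
  planted <- detectCompleteLD(panel)
  expect_length(planted, 2)
  expect_setequal(lapply(planted, function(g) sort(g$markers)),
                  list(c("qtl3A_a", "qtl3A_b"),
                       c("qtl4A_ld_a", "qtl4A_ld_b")))
})

test_that("marker panels round-trip through CSV", {
  sim <- simulatePanel(simulationConfig(), seed = 2)
  tmp <- withr::local_tempdir()
  callsPath <- file.path(tmp, "calls.csv")
  calls <- t(markerCalls(sim$panel))
  write.csv(data.frame(genotype_id = rownames(calls), calls,
                       check.names = FALSE),
            callsPath, row.names = FALSE)
  metaPath <- file.path(tmp, "meta.csv")
  write.csv(markerInfo(sim$panel), metaPath, row.names = FALSE)
  back <- readMarkerPanel(callsPath, metaPath)
  expect_identical(markerCalls(back), markerCalls(sim$panel))
  expect_equal(markerInfo(back)$strand_flag,
               markerInfo(sim$panel)$strand_flag)
})
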