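toy_records <- function(domain, peptide, kd = NA_real_, label = NA_integer_,
                        source = "src") {
  data.frame(domain_id = domain, peptide = peptide, kd_nM = kd,
             label = label, source = source, stringsAsFactors = FALSE)
}

test_that("K_d thresholding labels binding below 2000 nM, strictly", {
  expect_identical(label_from_kd(c(160, 2000, 3500, 1999.9)),
                   c(1L, -1L, -1L, 1L))
  expect_error(label_from_kd(0), "positive")
  expect_error(label_from_kd(-5), "positive")
  expect_error(label_from_kd(NA_real_))
})

test_that("cross-source conflicts are removed from both sides", {
  recs <- rbind(
    toy_records("D", "AAYAAAA", label = 1L, source = "s1"),
    toy_records("D", "AAYAAAA", label = -1L, source = "s2"))
  rc <- resolve_conflicts(recs)
  expect_identical(nrow(rc$records), 0L)
  expect_identical(rc$n_conflicts, 1L)
  # same-label duplicates collapse without discarding
  recs2 <- rbind(
    toy_records("D", "AAYAAAA", label = 1L, source = "s1"),
    toy_records("D", "AAYAAAA", label = 1L, source = "s2"))
  rc2 <- resolve_conflicts(recs2)
  expect_identical(nrow(rc2$records), 1L)
  expect_identical(rc2$n_conflicts, 0L)
  expect_identical(rc2$n_duplicates, 1L)
})

test_that("a toy table with two conflicting pairs keeps six records", {
  peps <- paste0(LETTERS[1:5], "AY", "AAA", LETTERS[1:5])
  recs <- rbind(
    toy_records("D1", peps[1], label = 1L, source = "s1"),   # conflict 1
    toy_records("D1", peps[1], label = -1L, source = "s2"),
    toy_records("D1", peps[2], label = 1L, source = "s1"),   # conflict 2
    toy_records("D1", peps[2], label = -1L, source = "s2"),
    toy_records("D1", peps[3], label = 1L, source = "s1"),
    toy_records("D1", peps[4], label = -1L, source = "s1"),
    toy_records("D2", peps[1], label = 1L, source = "s1"),   # other domain
    toy_records("D2", peps[3], label = -1L, source = "s2"),
    toy_records("D2", peps[4], label = 1L, source = "s1"),
    toy_records("D2", peps[5], label = -1L, source = "s1"))
  rc <- resolve_conflicts(recs)
  expect_identical(nrow(rc$records), 6L)
  expect_identical(rc$n_conflicts, 2L)
  # conservation and idempotence
  expect_identical(nrow(recs),
                   nrow(rc$records) + rc$n_conflict_rows + rc$n_duplicates)
  rc2 <- resolve_conflicts(rc$records)
  expect_identical(rc2$records, rc$records)
  expect_identical(rc2$n_conflicts, 0L)
})

test_that("explicit labels win over disagreeing K_d with a warning", {
  recs <- toy_records("D", "AAYAAAA", kd = 100, label = -1L)
  expect_warning(out <- sh2pep:::label_records(recs), "disagreeing")
  expect_identical(out$label, -1L)
})

test_that("positives already in the primary source are deduplicated", {
  primary <- rbind(toy_records("D", "AAYAAAA", label = 1L, source = "p"),
                   toy_records("D", "CCYAAAA", label = 1L, source = "p"))
  other <- rbind(toy_records("D", "CCYAAAA", label = 1L, source = "o"),
                 toy_records("D", "DDYAAAA", label = 1L, source = "o"))
  dd <- deduplicate_positives(primary, other)
  expect_identical(dd$other_unique$peptide, "DDYAAAA")
  expect_identical(dd$counts$n_shared, 1L)
  expect_identical(dd$counts$n_unique, 1L)
})

test_that("domain retention threshold is 'fewer than', boundary kept", {
  set.seed(1)
  mk <- function(n) encode_peptides(sh2pep:::random_windows(n))
  ds <- list(
    A = structure(list(domain_id = "A", positives = mk(39), negatives = mk(5),
                       unlabeled = NULL, scheme = "full20"),
                  class = "sh2_dataset"),
    B = structure(list(domain_id = "B", positives = mk(40), negatives = mk(5),
                       unlabeled = NULL, scheme = "full20"),
                  class = "sh2_dataset"))
  flt <- filter_domains(ds)
  expect_identical(names(flt$datasets), "B")
  expect_identical(flt$report$retained, c(FALSE, TRUE))
})

test_that("survey simulation replays its marginal arithmetic at small scale", {
  tabs <- simulate_survey_tables(seed = 2, n_domains = 8, n_peptides = 60,
                                 n_pos = 250, grid2 = c(10, 8, 20, 12),
                                 grid3 = c(9, 10, 25, 15), n_conflicts = 10,
                                 n_small_domains = 2, small_domain_pos = 5)
  expect_identical(nrow(tabs$peptide_array), 250L)
  expect_identical(nrow(tabs$microarray2), 80L)
  expect_identical(nrow(tabs$microarray3), 90L)
  lab2 <- sh2pep:::label_records(tabs$microarray2)
  lab3 <- sh2pep:::label_records(tabs$microarray3)
  expect_identical(sum(lab2$label > 0), 20L)
  expect_identical(sum(lab3$label > 0), 25L)
  dd <- deduplicate_positives(tabs$peptide_array,
                              rbind(lab2, lab3)[c(lab2$label, lab3$label) > 0, ])
  expect_identical(dd$counts$n_unique, c(8L, 10L))
  rc <- resolve_conflicts(rbind(tabs$peptide_array, tabs$microarray2,
                                tabs$microarray3))
  expect_identical(rc$n_conflicts, 10L)
  pa_left <- sum(rc$records$source == "peptide_array" & rc$records$label > 0)
  expect_identical(pa_left, 250L - 10L)
})
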