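test_that("percentage reproduces report arithmetic with half-up rounding", {
  expect_equal(percentage(640, 1046, 2), 61.19)
  expect_equal(percentage(99, 231, 1), 42.9)
  expect_equal(percentage(0, 50, 2), 0)
  expect_equal(percentage(5, 8, 0), 63)      # 62.5 rounds up, not to even
  expect_equal(percentage(1, 8, 1), 12.5)
  expect_true(is.na(percentage(0, 0)))       # undefined, never silent 0
  expect_error(percentage(5, 4), "exceeds")
  expect_error(percentage(-1, 4), "non-negative")
})

test_that("follow-up rates match hand tallies overall and per site", {
  n <- 1046
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    screening_record(participant_id = sprintf("PT%05d", i))
  }))
  fu <- data.frame(participant_id = sprintf("PT%05d", 1:538),
                   followed_up = TRUE,
                   follow_up_date = "2016-01-01",
                   recording_provider = "S1_GP", stringsAsFactors = FALSE)
  expect_equal(follow_up_rate(recs, fu), 51.43)
  fu_all <- data.frame(participant_id = recs$participant_id,
                       followed_up = TRUE, follow_up_date = "2016-01-01",
                       recording_provider = "S1_GP", stringsAsFactors = FALSE)
  expect_equal(follow_up_rate(recs, fu_all), 100)
  expect_true(is.na(follow_up_rate(recs, fu, ids = character())))

  # per-site rates spanning a wide range, against per-site counting
  sites <- data.frame(site = c("A", "B", "C"), n = c(38, 50, 90),
                      followed = c(4, 25, 77))
  recs2 <- do.call(rbind, lapply(seq_len(nrow(sites)), function(s) {
    do.call(rbind, lapply(seq_len(sites$n[s]), function(i) {
      screening_record(participant_id = sprintf("%s%03d", sites$site[s], i),
                       event_id = sites$site[s])
    }))
  }))
  fu2 <- data.frame(
    participant_id = unlist(lapply(seq_len(nrow(sites)), function(s) {
      sprintf("%s%03d", sites$site[s], seq_len(sites$followed[s]))
    })),
    followed_up = TRUE, follow_up_date = "2016-01-01",
    recording_provider = "X", stringsAsFactors = FALSE)
  for (s in seq_len(nrow(sites))) {
    ids <- recs2$participant_id[recs2$event_id == sites$site[s]]
    expect_equal(follow_up_rate(recs2, fu2, ids),
                 percentage(sites$followed[s], sites$n[s], 2))
  }
  expect_equal(follow_up_rate(recs2, fu2, recs2$participant_id[recs2$event_id == "A"]),
               10.53)  # 4/38
  expect_equal(follow_up_rate(recs2, fu2, recs2$participant_id[recs2$event_id == "C"]),
               85.56)  # 77/90
})

test_that("event report tallies agree with direct counting of the cohort", {
  cohort <- generate_cohort(cohort_spec(n_per_site = c(120, 80, 100)),
                            seed = 23)
  prof <- screen_cohort(cohort)
  cg <- assess_care_gaps(cohort, prof)
  fu <- generate_followups(cohort, prof, seed = 23)
  rep <- event_report(cohort, prof, cg, fu)

  expect_equal(rep$overall$n_screened, 300)
  expect_equal(rep$overall$n_sites, 3)
  expect_equal(rep$overall$n_female, sum(cohort$sex == "female"))
  expect_equal(rep$overall$pct_female,
               percentage(sum(cohort$sex == "female"), 300, 2))

  # category blocks carry both counts and the recomputable percentage
  for (blk in list(rep$cvd_categories, rep$diabetes_categories)) {
    expect_equal(sum(blk$n), 300)                    # partition invariant
    expect_equal(blk$pct, percentage(blk$n, rep(300, nrow(blk)), 2))
  }
  # under-30s land in under_30 unless a history/clinical rule outranks it
  young <- cohort$age < 30
  expect_true(all(prof$cvd_category[young] %in%
                    c("under_30", "established_cvd", "clinically_high")))
  expect_equal(rep$cvd_categories$n[rep$cvd_categories$category == "under_30"],
               sum(young & prof$cvd_category == "under_30"))

  # lifestyle prevalences equal direct tallies of the generator's records
  ls <- rep$lifestyle_by_sex
  smk_f <- ls[ls$sex == "female" & ls$flag == "current_smoker", ]
  expect_equal(smk_f$n, sum(cohort$smoking_status == "current" &
                              cohort$sex == "female", na.rm = TRUE))
  expect_equal(smk_f$denominator, sum(cohort$sex == "female"))
  expect_equal(smk_f$pct, percentage(smk_f$n, smk_f$denominator, 1))

  # care-gap and follow-up blocks reconcile with their counts
  expect_equal(rep$care$cvd$pct_on_recommended,
               percentage(rep$care$cvd$n_on_recommended,
                          rep$care$cvd$n_applicable, 1))
  expect_equal(rep$followup$pct_followed,
               percentage(rep$followup$n_followed, 300, 2))
})

test_that("nine sites with the published attendance average 116 per site", {
  spec <- cohort_spec()  # default per-site n: 132,114,107,118,77,119,123,127,129
  cohort <- generate_cohort(spec, seed = 3)
  prof <- screen_cohort(cohort)
  rep <- event_report(cohort, prof)
  expect_equal(rep$overall$n_screened, 1046)
  expect_equal(rep$by_site$n, spec$n_per_site)
  expect_equal(rep$overall$mean_screened_per_site, 116.2)  # 1046 / 9
})

test_that("an empty cohort reports n = 0 with undefined rates", {
  empty <- generate_cohort(cohort_spec(n_per_site = 0, n_sites = 1))
  prof <- screen_cohort(empty)
  rep <- event_report(empty, prof)
  expect_equal(rep$overall$n_screened, 0)
  expect_true(is.na(rep$overall$pct_female))
  expect_true(all(is.na(rep$cvd_categories$pct)))
})

test_that("orphan follow-up records surface in the report appendix", {
  cohort <- generate_cohort(cohort_spec(n_per_site = 20, n_sites = 1), seed = 2)
  prof <- screen_cohort(cohort)
  fu <- generate_followups(cohort, prof, seed = 2)
  fu <- rbind(fu, data.frame(participant_id = "GHOST1", followed_up = TRUE,
                             follow_up_date = "2016-02-02",
                             recording_provider = "S1_GP"))
  rep <- event_report(cohort, prof, followups = fu)
  expect_equal(rep$appendix$orphan_followups$participant_id, "GHOST1")
})

test_that("the portal sort puts unfollowed high-risk participants first", {
  prof <- screen_cohort(rbind(
    screening_record(participant_id = "A_low"),
    screening_record(participant_id = "B_cvd_unf", hx_chd = TRUE),
    screening_record(participant_id = "C_cvd_fol", hx_chd = TRUE)
  ))
  fu <- data.frame(participant_id = "C_cvd_fol", followed_up = TRUE,
                   follow_up_date = "2016-01-01", recording_provider = "X",
                   stringsAsFactors = FALSE)
  got <- prioritize_followup(prof, fu)
  expect_equal(got$participant_id, c("B_cvd_unf", "A_low", "C_cvd_fol"))
})

test_that("identical profiles sort by participant id", {
  recs <- do.call(rbind, lapply(c("P3", "P1", "P2"), function(id) {
    screening_record(participant_id = id)
  }))
  prof <- screen_cohort(recs)
  expect_equal(prioritize_followup(prof, NULL)$participant_id,
               c("P1", "P2", "P3"))
})

test_that("the sort is a deterministic permutation matching the brute-force comparator", {
  recs <- grid_records(200, seed = 31)
  prof <- screen_cohort(recs)
  set.seed(32)
  followed <- sample(prof$participant_id, 80)
  fu <- data.frame(participant_id = followed, followed_up = TRUE,
                   follow_up_date = "2016-01-01", recording_provider = "X",
                   stringsAsFactors = FALSE)
  got <- prioritize_followup(prof, fu)
  expect_setequal(got$participant_id, prof$participant_id)  # permutation
  expect_identical(got, prioritize_followup(prof, fu))      # repeatable
  expect_equal(got$participant_id, oracle_priority_sort(prof, followed))
})
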