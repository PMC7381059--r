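test_that("registry gold standard groups records by auxiliary person ID", {
  # 28 persons with 2 records each plus singletons
  recs <- data.frame(record_id = sprintf("r%03d", 1:70))
  registry <- data.frame(person_id = rep(sprintf("p%02d", 1:28), each = 2),
                         record_id = sprintf("r%03d", 1:56))
  gold <- build_gold_registry(recs, registry)
  expect_equal(length(gold$linked_ids), 56)
  expect_equal(length(unique(gold$clusters[gold$linked_ids])), 28)
  expect_equal(length(gold$unlinked_ids), 14)

  empty <- build_gold_registry(recs, registry[0, ])
  expect_equal(length(empty$unlinked_ids), 70)

  trio <- build_gold_registry(recs, data.frame(person_id = "p1",
                                               record_id = c("r001", "r002",
                                                             "r003")))
  expect_equal(sum(trio$clusters == trio$clusters[["r001"]]), 3)

  conflict <- data.frame(person_id = c("p1", "p2"), record_id = "r001")
  expect_error(build_gold_registry(recs, conflict), "conflict")
})

test_that("specimen gold standard enforces ID, year of birth and the 7-day window", {
  recs <- data.frame(record_id = c("c1", "c2", "c3", "l1", "l2", "l3"),
                     birth_year = c(1980L, 1980L, 1985L, 1980L, 1980L, 1980L))
  clinic <- data.frame(record_id = c("c1", "c2", "c3"),
                       specimen_id = c("s1", "s2", "s3"),
                       test_date = as.Date(c("2015-01-01", "2015-01-01",
                                             "2015-01-01")))
  lab <- data.frame(record_id = c("l1", "l2", "l3"),
                    specimen_id = c("s1", "s2", "s3"),
                    test_date = as.Date(c("2015-01-08",   # 7 days: in
                                          "2015-01-09",   # 8 days: out
                                          "2015-01-02")))
  gold <- build_gold_specimen(clinic, lab, recs)
  # s1 matched at the inclusive boundary; s2 beyond it; s3 fails on year
  expect_setequal(names(gold$clusters), c("c1", "l1"))
  expect_equal(gold$clusters[["c1"]], gold$clusters[["l1"]])
  expect_equal(length(gold$unlinked_ids), 0)

  # shared specimen chains union transitively
  lab2 <- rbind(lab[1, ], data.frame(record_id = "l9", specimen_id = "s1",
                                     test_date = as.Date("2015-01-03")))
  recs2 <- rbind(recs, data.frame(record_id = "l9", birth_year = 1980L))
  gold2 <- build_gold_specimen(clinic, lab2, recs2)
  expect_equal(length(unique(gold2$clusters[c("c1", "l1", "l9")])), 1)
})

test_that("scoring reproduces the count arithmetic on a missed-pair instance", {
  # 28 gold pairs among 3700 records; the tool misses one pair
  n_single <- 3644
  ids <- c(sprintf("g%03d", 1:56), sprintf("u%04d", 1:n_single))
  gold_cl <- c(rep(sprintf("p%02d", 1:28), each = 2), sprintf("u%04d", 1:n_single))
  names(gold_cl) <- ids
  tool_cl <- gold_cl
  tool_cl[c("g001", "g002")] <- c("g001", "g002")  # the missed pair
  report <- score_linkage(as_result(tool_cl, "two_or_more_keys"),
                          as_gold(gold_cl))
  expect_equal(report$n_correctly_linked, 54)
  expect_equal(report$sensitivity_pct, 96.43)
  expect_equal(round_half_up(report$sensitivity_pct), 96)
  expect_equal(report$n_correctly_unlinked, 3644)
  expect_equal(report$specificity_pct, 100)
  expect_equal(report$ppv_pct, 100)
  expect_equal(report$n_tool_unlinked, 3646)

  # tool links nothing at all: zero sensitivity, perfect specificity
  nothing <- stats::setNames(ids, ids)
  rep0 <- score_linkage(as_result(nothing), as_gold(gold_cl))
  expect_equal(rep0$sensitivity_pct, 0)
  expect_equal(rep0$specificity_pct, 100)
  expect_true(is.na(rep0$ppv_pct))  # no tool-linked records

  # record-set mismatch is an error
  expect_error(score_linkage(as_result(tool_cl[-1]), as_gold(gold_cl)),
               "cover")
})

test_that("scoring agrees with the enumeration oracle on random instances", {
  set.seed(77)
  for (i in 1:10) {
    n <- 60
    ids <- sprintf("r%03d", 1:n)
    gold_cl <- stats::setNames(sprintf("g%d", sample.int(25, n, TRUE)), ids)
    tool_cl <- stats::setNames(sprintf("t%d", sample.int(25, n, TRUE)), ids)
    got <- score_linkage(as_result(tool_cl), as_gold(gold_cl))
    want <- brute_force_score(tool_cl, gold_cl)
    expect_equal(got$n_correctly_linked, unname(want$correctly_linked))
    expect_equal(got$n_correctly_unlinked, unname(want$correctly_unlinked))
    expect_equal(got$n_tool_linked_correct, unname(want$tool_linked_correct))
    expect_equal(got$n_tool_unlinked_correct, unname(want$tool_unlinked_correct))
    expect_equal(got$n_gold_linked, unname(want$gold_linked))
    expect_equal(got$n_tool_linked, unname(want$tool_linked))
  }
})

test_that("all-co-members scoring is stricter than any-co-member", {
  ids <- c("a1", "a2", "a3", "b1")
  gold_cl <- stats::setNames(c("p", "p", "p", "b1"), ids)
  tool_cl <- stats::setNames(c("x", "x", "y", "y"), ids)   # a3 split off
  lenient <- score_linkage(as_result(tool_cl), as_gold(gold_cl))
  strict <- score_linkage(as_result(tool_cl), as_gold(gold_cl),
                          all_comembers = TRUE)
  expect_equal(lenient$n_correctly_linked, 2)  # a1, a2 keep one co-member
  expect_equal(strict$n_correctly_linked, 0)
})

audit_fixture <- function(rows, clusters, analyte_class = "HIV") {
  tests <- do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r[[1]], analyte = r[[2]], result = r[[3]],
               test_date = as.Date("2015-01-01") + as.integer(r[[4]]),
               stringsAsFactors = FALSE)
  }))
  serology_audit(as_result(clusters), tests, analyte_class)
}

test_that("serology audit flags negatives at least a week after a positive", {
  cl <- stats::setNames(c("A", "A"), c("r1", "r2"))
  # western blot positive day 0, antibody negative day 10: discordant
  aud <- audit_fixture(list(c("r1", "HIV_WB", "positive", 0),
                            c("r1", "HIV_AB", "positive", 0),
                            c("r2", "HIV_AB", "negative", 10),
                            c("r1", "HIV_AB", "positive", 15)), cl)
  expect_equal(aud$n_linked_with_initial_positive, 2)
  expect_equal(aud$n_concordant, 1)
  expect_equal(aud$ppv_pct, 50)
  # subsequent results split 1/1: no negative majority, the discordant
  # negative record is the intruder
  expect_equal(aud$flagged$record_id[aud$flagged$attributed_wrong], "r2")

  # negative only 3 days after the positive: within the window, concordant
  aud2 <- audit_fixture(list(c("r1", "HIV_WB", "positive", 0),
                             c("r2", "HIV_AB", "negative", 3)), cl)
  expect_equal(aud2$n_concordant, 2)
  expect_equal(aud2$ppv_pct, 100)
})

test_that("a majority of subsequent negatives reattributes the positives", {
  cl <- stats::setNames(c("A", "A", "A", "A"), c("r1", "r2", "r3", "r4"))
  aud <- audit_fixture(list(c("r1", "HCV_AB", "positive", 0),
                            c("r2", "HCV_AB", "negative", 30),
                            c("r3", "HCV_AB", "negative", 60),
                            c("r4", "HCV_AB", "negative", 90)),
                       cl, "HCV")
  # three of three subsequent antibody results negative: the positive record
  # is the intruder
  wrong <- aud$flagged$record_id[aud$flagged$attributed_wrong]
  expect_equal(wrong, "r1")
  expect_equal(aud$n_concordant, 3)
  expect_equal(aud$ppv_pct, 75)
})

test_that("records discordant before linkage are excluded from the audit", {
  # r1's own history is discordant (negative 20 days after its positive);
  # the cluster must not be blamed on linkage
  cl <- stats::setNames(c("A", "A"), c("r1", "r2"))
  aud <- audit_fixture(list(c("r1", "HIV_WB", "positive", 0),
                            c("r1", "HIV_AB", "negative", 20),
                            c("r2", "HIV_AB", "positive", 5)), cl)
  expect_equal(aud$n_excluded_pre, 1)
  # with r1 gone the cluster has no initial western blot left: nothing retained
  expect_equal(aud$n_linked_with_initial_positive, 0)
  expect_true(is.na(aud$ppv_pct))
})

test_that("clusters without an initial positive or later antibody are not retained", {
  cl <- stats::setNames(c("A", "A", "B", "B"), c("r1", "r2", "r3", "r4"))
  aud <- audit_fixture(list(
    c("r1", "HIV_AB", "negative", 0),   # cluster A: never positive
    c("r2", "HIV_AB", "negative", 50),
    c("r3", "HIV_WB", "positive", 10),  # cluster B: positive but no later AB
    c("r3", "HIV_AB", "positive", 10)), cl)
  expect_equal(aud$n_linked_with_initial_positive, 0)
  expect_true(is.na(aud$ppv_pct))
})

test_that("specificity estimation inverts the Bayes identity", {
  expect_equal(estimate_specificity(1, 1, 0.3), 1)
  # round trip: forward PPV from (Se, Sp, pi), then invert
  for (se in c(0.7, 0.9, 1)) {
    for (sp in c(0.8, 0.95, 0.99)) {
      for (prev in c(0.1, 0.3, 0.5)) {
        ppv <- se * prev / (se * prev + (1 - sp) * (1 - prev))
        expect_equal(estimate_specificity(ppv, se, prev), sp,
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(estimate_specificity(0, 0.9, 0.3), "ppv")
  expect_error(estimate_specificity(0.9, 1.2, 0.3), "sensitivity")
  expect_error(estimate_specificity(0.9, 0.9, 1), "prevalence")
  # clamped at zero when the inputs imply an impossible specificity
  expect_equal(estimate_specificity(0.01, 1, 0.9), 0)
})
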