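clean_sites <- function(n_clinics = 2, n_labs = 1, vp = 0.5,
                        medicare_missing = 0) {
  data.frame(
    site_id = c(sprintf("clinic%d", seq_len(n_clinics)),
                if (n_labs) sprintf("lab%d", seq_len(n_labs))),
    site_type = c(rep("clinic", n_clinics), rep("laboratory", n_labs)),
    visit_probability = c(rep(vp, n_clinics), rep(1, n_labs)),
    medicare_missing_rate = medicare_missing,
    name_typo_rate = 0, nickname_rate = 0, dob_transpose_rate = 0,
    partial_dob_rate = 0, stringsAsFactors = FALSE
  )
}

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(150, sites = clean_sites(), rng_seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$identified, b$identified)
  expect_identical(a$tests, b$tests)
  expect_identical(a$truth, b$truth)

  c2 <- generate_cohort(cohort_config(150, sites = clean_sites(),
                                      rng_seed = 100))
  expect_false(identical(a$identified, c2$identified))
})

test_that("truth and specimen flows are internally consistent", {
  ch <- generate_cohort(cohort_config(200, rng_seed = 7))
  # every record exactly once in the truth table, matching the EMR table
  expect_equal(anyDuplicated(ch$truth$record_id), 0)
  expect_setequal(ch$truth$record_id, ch$identified$record_id)
  # each specimen: exactly one clinic record, at least one lab record
  site_type <- stats::setNames(ch$identified$site_type,
                               ch$identified$record_id)
  spec <- split(site_type[ch$tests$record_id], ch$tests$specimen_id)
  expect_true(all(vapply(spec, function(s) {
    length(unique(names(s)[s == "clinic"])) == 1 &&
      length(unique(names(s)[s == "laboratory"])) >= 1
  }, logical(1))))
  # every person owns at least one EMR
  expect_setequal(unique(ch$truth$person_id), ch$persons$person_id)
})

test_that("serology is consistent with infection status within every person", {
  ch <- generate_cohort(cohort_config(300, hiv_prevalence = 0.3,
                                      hcv_prevalence = 0.3, rng_seed = 21))
  person_of <- stats::setNames(ch$truth$person_id, ch$truth$record_id)
  tst <- ch$tests
  tst$person <- person_of[tst$record_id]
  for (cls in c("HIV", "HCV")) {
    ab <- tst[tst$analyte == paste0(cls, "_AB"), ]
    by_p <- split(ab, ab$person)
    violations <- vapply(by_p, function(x) {
      pos <- x$test_date[x$result == "positive"]
      neg <- x$test_date[x$result == "negative"]
      length(pos) && length(neg) && max(neg) >= min(pos)
    }, logical(1))
    expect_false(any(violations), label = cls)
  }
})

test_that("uncorrupted identifiers let every approach recover the truth exactly", {
  ch <- generate_cohort(cohort_config(150, sites = clean_sites(),
                                      duplicate_emr_rate = 0.1,
                                      tests_per_person = c(0, 2),
                                      rng_seed = 31))
  keys <- generate_keysets(prepare_identities(ch$identified),
                           test_keygen_config())
  gold <- build_gold_registry(keys, ch$registry)
  expect_gt(length(gold$linked_ids), 0)
  expect_gt(length(gold$unlinked_ids), 0)
  for (app in linkage_approaches()) {
    rep <- score_linkage(link_records(keys, app), gold)
    expect_equal(rep$sensitivity_pct, 100, label = app)
    expect_equal(rep$specificity_pct, 100, label = app)
    expect_equal(rep$ppv_pct, 100, label = app)
    expect_equal(rep$npv_pct, 100, label = app)
  }
})

test_that("per-site Medicare blanking restricts records to key type 3", {
  sites <- clean_sites(n_clinics = 2, n_labs = 1)
  sites$medicare_missing_rate[sites$site_id == "lab1"] <- 0.97
  ch <- generate_cohort(cohort_config(400, sites = sites, rng_seed = 17))
  keys <- generate_keysets(prepare_identities(ch$identified),
                           test_keygen_config())
  at_lab <- keys[keys$site_id == "lab1", ]
  only3 <- is.na(at_lab$key1) & is.na(at_lab$key2) & is.na(at_lab$key4) &
    !is.na(at_lab$key3)
  rate <- mean(only3)
  se <- sqrt(0.97 * 0.03 / nrow(at_lab))
  expect_lt(abs(rate - 0.97), 2 * se + 1e-9)
})

test_that("name corruption follows the configured phonetic-break split", {
  sites <- clean_sites(n_clinics = 1, n_labs = 0)
  sites$name_typo_rate <- 1
  sites$visit_probability <- 1
  base <- cohort_config(120, sites = sites, tests_per_person = c(0, 0),
                        duplicate_emr_rate = 0, typo_phonetic_break_prob = 0,
                        rng_seed = 5)
  ch <- generate_cohort(base)
  # with only phonetic-preserving typos, key3 still matches the clean truth
  person <- ch$persons
  clean_raw <- data.frame(record_id = person$person_id, site_id = "x",
                          site_type = "clinic",
                          first_name = person$first_name,
                          last_name = person$last_name,
                          birth_day = person$birth_day,
                          birth_month = person$birth_month,
                          birth_year = person$birth_year, sex = person$sex,
                          postcode = person$postcode,
                          medicare_number = person$medicare_number,
                          stringsAsFactors = FALSE)
  cfg <- test_keygen_config()
  clean_k3 <- stats::setNames(
    generate_keysets(prepare_identities(clean_raw), cfg)$key3,
    person$person_id)
  emr_k3 <- generate_keysets(prepare_identities(ch$identified), cfg)$key3
  person_of <- stats::setNames(ch$truth$person_id, ch$truth$record_id)
  expect_equal(unname(clean_k3[person_of[ch$identified$record_id]]), emr_k3)
})

test_that("false-link injection perturbs only across clusters at the given rate", {
  clusters <- stats::setNames(rep(sprintf("p%03d", 1:100), each = 2),
                              sprintf("r%03d", 1:200))
  set.seed(1)
  same <- inject_false_links(clusters, 0)
  # labels may change (smallest-member rule) but the partition must not
  partition <- function(cl) unname(lapply(split(names(cl), cl), sort))
  expect_setequal(partition(same$clusters), partition(clusters))
  expect_equal(nrow(same$injected_pairs), 0)

  set.seed(2)
  perturbed <- inject_false_links(clusters, 0.2)
  inj <- perturbed$injected_pairs
  expect_gt(nrow(inj), 0)
  # injected pairs crossed cluster boundaries and are now unioned
  expect_true(all(clusters[inj$record_id_a] != clusters[inj$record_id_b]))
  expect_true(all(perturbed$clusters[inj$record_id_a] ==
                    perturbed$clusters[inj$record_id_b]))
  # injected count behaves binomially (0.2 * 200 = 40 expected)
  expect_lt(abs(nrow(inj) - 40), 4 * sqrt(200 * 0.2 * 0.8))
})

test_that("an injected serodiscordant pair is caught by the audit", {
  # two singleton persons, one HIV positive with a confirmed early positive,
  # one negative tested later: the injected link is flagged
  tests <- data.frame(
    record_id = c("rP", "rP", "rP", "rN"),
    analyte = c("HIV_WB", "HIV_AB", "HIV_AB", "HIV_AB"),
    result = c("positive", "positive", "positive", "negative"),
    test_date = as.Date(c("2015-01-01", "2015-01-01", "2015-03-01",
                          "2015-06-01")),
    stringsAsFactors = FALSE
  )
  clusters <- stats::setNames(c("rP", "rN"), c("rP", "rN"))
  set.seed(3)
  pert <- inject_false_links(clusters, 0.5, eligible_a = "rN",
                             eligible_b = "rP")
  if (nrow(pert$injected_pairs)) {
    aud <- serology_audit(as_result(pert$clusters), tests, "HIV")
    expect_equal(aud$n_linked_with_initial_positive, 2)
    expect_equal(aud$flagged$record_id[aud$flagged$attributed_wrong], "rN")
  }
})

test_that("infeasible configurations are rejected", {
  no_clinic <- clean_sites(n_clinics = 1, n_labs = 1)
  no_clinic$site_type <- "laboratory"
  expect_error(cohort_config(10, sites = no_clinic, rng_seed = 1), "clinic")
  expect_error(cohort_config(10, rng_seed = NA), "rng_seed")
  bad <- clean_sites()
  bad$medicare_missing_rate <- 1.2
  expect_error(cohort_config(10, sites = bad, rng_seed = 1), "rate")
})
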