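# Simulation studies exercising the linkage pipeline end to end. Sourced by
# the test suite and by scripts/acceptance.R so both drive exactly the same
# experiments. Only exported hashlink functions are used.
#
# Problem sizes: the clean-cohort study uses 1,000 persons, the missingness
# study 1,200, and the estimator-recovery study a 10,000-record population
# (2,500 duplicated persons plus 5,000 singletons); these are the study
# conditions, chosen so that binomial standard errors on the reported
# percentages are a fraction of a percent.

# uncorrupted multi-site cohort: every approach must recover the truth
study_clean_cohort <- function(seed, n_persons = 1000) {
  sites <- data.frame(
    site_id = c("clinic1", "clinic2", "clinic3", "lab1", "lab2"),
    site_type = c(rep("clinic", 3), rep("laboratory", 2)),
    visit_probability = c(0.3, 0.3, 0.2, 0.6, 0.4),
    medicare_missing_rate = 0, name_typo_rate = 0, nickname_rate = 0,
    dob_transpose_rate = 0, partial_dob_rate = 0, stringsAsFactors = FALSE
  )
  cohort <- generate_cohort(cohort_config(
    n_persons, sites = sites, duplicate_emr_rate = 0.05,
    tests_per_person = c(0, 2), rng_seed = seed))
  keys <- generate_keysets(prepare_identities(cohort$identified),
                           keygen_config(paste0("study-secret-", seed)))
  gold <- build_gold_registry(keys, cohort$registry)
  reports <- lapply(linkage_approaches(), function(app) {
    score_linkage(link_records(keys, app), gold)
  })
  names(reports) <- linkage_approaches()
  list(reports = reports, n_records = nrow(keys), gold = gold)
}

# one laboratory blanks Medicare on 97% of its records (the public-lab
# condition): its records carry only key type 3 and multi-key matching
# loses the cross-site links
study_missingness <- function(seed, n_persons = 1200,
                              medicare_missing = 0.97) {
  sites <- data.frame(
    site_id = c("clinic1", "clinic2", "lab1"),
    site_type = c("clinic", "clinic", "laboratory"),
    visit_probability = c(0.6, 0.4, 1),
    medicare_missing_rate = c(0, 0, medicare_missing),
    name_typo_rate = 0, nickname_rate = 0, dob_transpose_rate = 0,
    partial_dob_rate = 0, stringsAsFactors = FALSE
  )
  cohort <- generate_cohort(cohort_config(
    n_persons, sites = sites, duplicate_emr_rate = 0,
    tests_per_person = c(1, 3), rng_seed = seed))
  keys <- generate_keysets(prepare_identities(cohort$identified),
                           keygen_config(paste0("study-secret-", seed)))
  at_lab <- keys[keys$site_id == "lab1", ]
  only_key3 <- is.na(at_lab$key1) & is.na(at_lab$key2) & is.na(at_lab$key4) &
    !is.na(at_lab$key3)
  gold <- build_gold_registry(keys, cohort$registry)
  rep_all <- score_linkage(link_records(keys, "accept_all"), gold)
  rep_two <- score_linkage(link_records(keys, "two_or_more_keys"), gold)
  list(
    n_lab_records = nrow(at_lab),
    n_gold_linked = rep_all$n_gold_linked,
    only_key3_rate = mean(only_key3),
    expected_rate = medicare_missing,
    rate_se = sqrt(medicare_missing * (1 - medicare_missing) / nrow(at_lab)),
    sensitivity_accept_all_pct = rep_all$sensitivity_pct,
    sensitivity_two_or_more_pct = rep_two$sensitivity_pct
  )
}

# estimator recovery: perfect linkage of a mixed cohort perturbed by false
# links that join serodiscordant persons with observable discordance; the
# discordance audit must recover the true PPV, and the Bayes inversion the
# directly measured specificity. The derived (auditable) population is the
# retained clusters plus all unlinked records, mirroring how a derived
# serology dataset is assembled in practice.
study_estimator <- function(seed, n_dup = 2500, n_single = 5000,
                            rate = 0.1) {
  two_clinics <- data.frame(
    site_id = c("clinicA", "clinicB"), site_type = "clinic",
    visit_probability = 1, medicare_missing_rate = 0, name_typo_rate = 0,
    nickname_rate = 0, dob_transpose_rate = 0, partial_dob_rate = 0,
    stringsAsFactors = FALSE
  )
  one_clinic <- two_clinics[1, ]
  # duplicated persons: all HIV-positive, several tests, two EMRs each
  coh_a <- generate_cohort(cohort_config(
    n_dup, sites = two_clinics, duplicate_emr_rate = 0, hiv_prevalence = 1,
    hcv_prevalence = 0, tests_per_person = c(3, 5), rng_seed = seed))
  # singleton persons: one EMR and one test event each, mixed serostatus
  coh_b <- generate_cohort(cohort_config(
    n_single, sites = one_clinic, duplicate_emr_rate = 0,
    hiv_prevalence = 0.5, hcv_prevalence = 0, tests_per_person = c(1, 1),
    rng_seed = seed + 1L))

  prefix <- function(cohort, tag) {
    cohort$identified$record_id <- paste0(tag, cohort$identified$record_id)
    cohort$truth$record_id <- paste0(tag, cohort$truth$record_id)
    cohort$truth$person_id <- paste0(tag, cohort$truth$person_id)
    cohort$tests$record_id <- paste0(tag, cohort$tests$record_id)
    cohort$persons$person_id <- paste0(tag, cohort$persons$person_id)
    cohort
  }
  coh_a <- prefix(coh_a, "A")
  coh_b <- prefix(coh_b, "B")
  truth <- rbind(coh_a$truth, coh_b$truth)
  tests <- rbind(coh_a$tests, coh_b$tests)
  clusters <- stats::setNames(truth$person_id, truth$record_id)

  # observable-discordance eligibility, computed from the tests tables:
  # targets are records of duplicated persons whose initial positive western
  # blot falls in the first half of the window and who have a later positive
  # antibody; intruders are HIV-negative singletons tested late
  cfg <- coh_a$config
  days <- as.integer(cfg$end_date - cfg$start_date)
  mid <- cfg$start_date + 0.5 * days
  late <- cfg$start_date + 0.7 * days

  person_of <- stats::setNames(truth$person_id, truth$record_id)
  wb <- tests[tests$analyte == "HIV_WB" & tests$result == "positive", ]
  t0 <- tapply(wb$test_date, person_of[wb$record_id], min)
  ab_pos <- tests[tests$analyte == "HIV_AB" & tests$result == "positive", ]
  ab_pos_person <- person_of[ab_pos$record_id]
  has_later_ab <- tapply(
    as.numeric(ab_pos$test_date) - as.numeric(t0[ab_pos_person]),
    ab_pos_person, function(d) any(d > 0))
  eligible_persons <- names(t0)[as.Date(t0, origin = "1970-01-01") <= mid]
  eligible_persons <- intersect(
    eligible_persons, names(has_later_ab)[which(has_later_ab)])
  eligible_b <- truth$record_id[truth$person_id %in% eligible_persons]

  neg_people <- coh_b$persons$person_id[!coh_b$persons$hiv_positive]
  late_tested <- unique(tests$record_id[tests$analyte == "HIV_AB" &
                                          tests$result == "negative" &
                                          tests$test_date >= late])
  eligible_a <- intersect(truth$record_id[truth$person_id %in% neg_people],
                          late_tested)

  pert <- inject_false_links(clusters, rate, eligible_a = eligible_a,
                             eligible_b = eligible_b)
  result <- structure(list(clusters = pert$clusters,
                           accepted_pairs = data.frame(),
                           approach = "perturbed_truth"),
                      class = "linkage_result")
  audit <- serology_audit(result, tests, "HIV")

  # derived population: audited clusters plus every unlinked record
  sizes <- table(pert$clusters)
  unlinked <- names(pert$clusters)[pert$clusters %in% names(sizes)[sizes == 1]]
  pop <- c(audit$retained_ids, unlinked)
  gold <- build_gold_registry(
    data.frame(record_id = pop, stringsAsFactors = FALSE),
    data.frame(person_id = unname(clusters[pop]), record_id = pop,
               stringsAsFactors = FALSE))
  report <- score_linkage(result, gold)

  true_ppv <- report$n_tool_linked_correct / report$n_tool_linked
  audit_ppv <- audit$ppv_pct / 100
  prevalence <- report$n_gold_linked / length(pop)
  sensitivity <- report$n_correctly_linked / report$n_gold_linked
  direct_spec <- report$n_correctly_unlinked / report$n_gold_unlinked
  est_spec <- estimate_specificity(audit_ppv, sensitivity, prevalence)

  list(
    n_records = length(clusters),
    n_retained = audit$n_linked_with_initial_positive,
    n_injected = nrow(pert$injected_pairs),
    audit_ppv = audit_ppv,
    true_ppv = true_ppv,
    ppv_se = sqrt(true_ppv * (1 - true_ppv) / report$n_tool_linked),
    estimated_specificity = est_spec,
    direct_specificity = direct_spec,
    spec_se = sqrt(direct_spec * (1 - direct_spec) / report$n_gold_unlinked),
    sensitivity = sensitivity,
    prevalence = prevalence
  )
}
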