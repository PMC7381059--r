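# Seeded synthetic multi-site EMR cohorts with ground truth. The generator
# emulates the identifier-quality conditions seen in sentinel surveillance
# networks: per-site Medicare missingness, name typos and aliases, day/month
# transpositions, partial birth dates, duplicate EMRs, clinic-to-laboratory
# specimen flows with small date jitter, and longitudinal HIV / hepatitis C
# serology consistent with each person's infection status (no assay errors,
# so any post-linkage discordance is attributable to wrong links).

#' Default site mix for the synthetic cohort
#'
#' Ships as an editable CSV (`extdata/default_sites.csv`): seven clinics with
#' high Medicare completeness, one sexual-health clinic recording Medicare
#' for roughly half of its patients, and four laboratories whose Medicare
#' completeness spans a few percent to near-complete.
#'
#' @return Data.frame of per-site rates; see [cohort_config()].
#' @export
default_sites <- function() {
  path <- system.file("extdata", "default_sites.csv", package = "hashlink")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_persons Number of distinct persons.
#' @param sites Data.frame with columns `site_id`, `site_type`
#'   (`clinic`/`laboratory`), `visit_probability` (per-person probability of
#'   attending a clinic; routing weight for a laboratory),
#'   `medicare_missing_rate`, `name_typo_rate`, `nickname_rate`,
#'   `dob_transpose_rate`, `partial_dob_rate` (all in `[0, 1]`, applied
#'   independently per EMR). Defaults to [default_sites()].
#' @param duplicate_emr_rate Probability that a person-site pairing yields a
#'   second, independently corrupted EMR at that site.
#' @param hiv_prevalence,hcv_prevalence Probability that a person is (or
#'   becomes, during the window) HIV / hepatitis C positive.
#' @param tests_per_person Integer range `c(min, max)` of test events per
#'   person.
#' @param specimen_date_jitter_days Maximum difference (0-7 days) between the
#'   clinic-recorded and laboratory-recorded date of one specimen.
#' @param typo_phonetic_break_prob Fraction of name typos that change the
#'   phonetic code (and therefore defeat fuzzy matching); the rest are
#'   misspellings that survive it.
#' @param start_date,end_date Observation window (ISO strings or Dates).
#' @param distinct_identities Resample so that no two persons share a
#'   (phonetic name pair, date of birth) signature or a Medicare number
#'   (default `TRUE`; guarantees that clean identifiers imply exact truth
#'   recovery).
#' @param rng_seed Mandatory integer seed; the outputs are a pure function of
#'   the configuration including this seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_persons,
                          sites = default_sites(),
                          duplicate_emr_rate = 0.03,
                          hiv_prevalence = 0.05,
                          hcv_prevalence = 0.05,
                          tests_per_person = c(1, 4),
                          specimen_date_jitter_days = 2,
                          typo_phonetic_break_prob = 0.5,
                          start_date = "2009-01-01",
                          end_date = "2018-04-30",
                          distinct_identities = TRUE,
                          rng_seed) {
  if (missing(rng_seed) || is.na(rng_seed)) stop("rng_seed is mandatory")
  stopifnot(n_persons >= 1, nrow(sites) >= 1)
  rate_cols <- c("visit_probability", "medicare_missing_rate",
                 "name_typo_rate", "nickname_rate", "dob_transpose_rate",
                 "partial_dob_rate")
  stopifnot(all(rate_cols %in% names(sites)))
  for (cc in rate_cols) {
    if (any(sites[[cc]] < 0 | sites[[cc]] > 1)) {
      stop("site rate out of [0, 1]: ", cc)
    }
  }
  if (!any(sites$site_type == "clinic")) stop("at least one clinic site required")
  stopifnot(duplicate_emr_rate >= 0, duplicate_emr_rate <= 1,
            hiv_prevalence >= 0, hiv_prevalence <= 1,
            hcv_prevalence >= 0, hcv_prevalence <= 1,
            specimen_date_jitter_days >= 0, specimen_date_jitter_days <= 7,
            typo_phonetic_break_prob >= 0, typo_phonetic_break_prob <= 1,
            length(tests_per_person) == 2, tests_per_person[1] >= 0,
            tests_per_person[2] >= tests_per_person[1])
  structure(list(
    n_persons = as.integer(n_persons), sites = sites,
    duplicate_emr_rate = duplicate_emr_rate,
    hiv_prevalence = hiv_prevalence, hcv_prevalence = hcv_prevalence,
    tests_per_person = as.integer(tests_per_person),
    specimen_date_jitter_days = as.integer(specimen_date_jitter_days),
    typo_phonetic_break_prob = typo_phonetic_break_prob,
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    distinct_identities = isTRUE(distinct_identities),
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

.name_pool <- function(which) {
  path <- system.file("extdata", paste0(which, ".csv"), package = "hashlink")
  toupper(utils::read.csv(path, stringsAsFactors = FALSE)$name)
}

# reverse nickname lookup: FORMAL -> list of nicknames
.nickname_reverse <- function(tab = default_nickname_table()) {
  split(names(tab), unname(tab))
}

# single-character edits used by the typo model. "Preserving" and "breaking"
# refer to the phonetic component that feeds the name+date key after the full
# canonicalization chain (cleaning and nickname resolution included), so a
# preserving typo survives fuzzy matching and a breaking one defeats it.
.canon_code <- function(name) {
  phonetic_encode(resolve_nickname(clean_name(name)))
}

.typo_preserving <- function(name) {
  # duplicate one letter; keep only edits that leave the canonical code intact
  code <- .canon_code(name)
  pos <- sample(seq_len(nchar(name)))
  for (i in pos) {
    cand <- paste0(substr(name, 1, i), substr(name, i, nchar(name)))
    if (identical(.canon_code(cand), code)) return(cand)
  }
  name
}

.typo_breaking <- function(name) {
  code <- .canon_code(name)
  cons <- strsplit("BCDFGKLMNPRSTZ", "")[[1]]
  for (try in 1:8) {
    i <- sample.int(nchar(name), 1)
    repl <- sample(cons, 1)
    cand <- paste0(substr(name, 1, i - 1), repl,
                   substr(name, i + 1, nchar(name)))
    if (cand != name && !identical(.canon_code(cand), code)) return(cand)
  }
  name
}

#' Generate a synthetic multi-site EMR cohort
#'
#' Each person attends at least one clinic; per-site corruption (Medicare
#' blanking, typos, nickname aliases, date transposition, partial dates) is
#' applied independently to every EMR; each clinic test event is mirrored to
#' a laboratory record sharing its specimen ID with a small date jitter; and
#' serology follows infection status exactly (negative before, positive from
#' the infection date on). Everything is reproducible from the seed in the
#' configuration.
#'
#' @param config A [cohort_config()].
#' @return A list with elements
#' * `identified` — identified-records table (one row per EMR, schema of
#'   [prepare_identities()]),
#' * `truth` — `record_id`, `person_id`,
#' * `tests` — `record_id`, `analyte`, `result`, `test_date`, `specimen_id`,
#' * `registry` — `person_id`, `record_id` (for the registry-style gold
#'   standard),
#' * `persons` — the person-level truth (identity, serostatus, infection
#'   dates).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  n <- config$n_persons
  sites <- config$sites
  clinics <- sites[sites$site_type == "clinic", , drop = FALSE]
  labs <- sites[sites$site_type == "laboratory", , drop = FALSE]

  first_pool <- .name_pool("first_names")
  last_pool <- .name_pool("surnames")
  nick_rev <- .nickname_reverse()

  days <- as.integer(config$end_date - config$start_date)

  persons <- data.frame(
    person_id = sprintf("p%06d", seq_len(n)),
    first_name = sample(first_pool, n, replace = TRUE),
    last_name = sample(last_pool, n, replace = TRUE),
    birth_year = sample(1940:2005, n, replace = TRUE),
    birth_month = sample(1:12, n, replace = TRUE),
    birth_day = sample(1:28, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    postcode = as.character(sample(3000:3999, n, replace = TRUE)),
    medicare_number = as.character(2000000000 + sample(999999999, n)),
    stringsAsFactors = FALSE
  )
  if (config$distinct_identities) {
    sig <- function(p) {
      f <- phonetic_encode(clean_name(p$first_name))
      l <- phonetic_encode(clean_name(p$last_name))
      paste(pmin(f, l), pmax(f, l),
            p$birth_year, p$birth_month, p$birth_day, sep = "|")
    }
    s <- sig(persons)
    for (iter in 1:25) {
      dup <- which(duplicated(s))
      if (!length(dup)) break
      persons$first_name[dup] <- sample(first_pool, length(dup), replace = TRUE)
      persons$last_name[dup] <- sample(last_pool, length(dup), replace = TRUE)
      persons$birth_day[dup] <- sample(1:28, length(dup), replace = TRUE)
      s <- sig(persons)
    }
    if (anyDuplicated(s)) stop("could not generate distinct identities; ",
                               "reduce n_persons or enlarge the name pools")
  }
  persons$hiv_positive <- stats::runif(n) < config$hiv_prevalence
  persons$hcv_positive <- stats::runif(n) < config$hcv_prevalence
  # infection dates sit in the first 60% of the window so that post-infection
  # tests can be observed
  inf_day <- function(flag) {
    d <- rep(as.Date(NA), n)
    d[flag] <- config$start_date + sample.int(max(1L, floor(days * 0.6)),
                                              sum(flag), replace = TRUE)
    d
  }
  persons$hiv_infection_date <- inf_day(persons$hiv_positive)
  persons$hcv_infection_date <- inf_day(persons$hcv_positive)

  # ---- clinic attendance ------------------------------------------------
  nc <- nrow(clinics)
  attend <- matrix(stats::runif(n * nc), n, nc) <
    matrix(clinics$visit_probability, n, nc, byrow = TRUE)
  home <- sample.int(nc, n, replace = TRUE,
                     prob = clinics$visit_probability /
                       sum(clinics$visit_probability))
  attend[cbind(seq_len(n), home)] <- TRUE
  pc <- which(attend, arr.ind = TRUE)  # (person, clinic) pairs
  attended_by_person <- split(pc[, 2L], pc[, 1L])

  # ---- test events and specimen routing ---------------------------------
  tp <- config$tests_per_person
  n_events <- if (tp[2] == tp[1]) rep.int(tp[1], n) else
    sample(tp[1]:tp[2], n, replace = TRUE)
  ev_person <- rep(seq_len(n), n_events)
  n_ev <- length(ev_person)
  ev_clinic <- vapply(ev_person, function(p) {
    cls <- attended_by_person[[as.character(p)]]
    if (length(cls) == 1L) cls else sample(cls, 1L)
  }, integer(1))
  ev_date <- config$start_date + sample.int(days, n_ev, replace = TRUE)
  ev_lab <- if (nrow(labs)) {
    sample.int(nrow(labs), n_ev, replace = TRUE,
               prob = labs$visit_probability / sum(labs$visit_probability))
  } else {
    rep(NA_integer_, n_ev)
  }
  ev_specimen <- sprintf("s%07d", seq_len(n_ev))
  ev_jitter <- if (config$specimen_date_jitter_days > 0) {
    sample.int(config$specimen_date_jitter_days + 1L, n_ev, replace = TRUE) - 1L
  } else {
    rep.int(0L, n_ev)
  }

  # ---- EMRs -------------------------------------------------------------
  pl <- unique(data.frame(person = ev_person, lab = ev_lab)[!is.na(ev_lab), ])
  emr <- rbind(
    data.frame(person = pc[, 1L],
               site_row = match(clinics$site_id[pc[, 2L]], sites$site_id)),
    if (nrow(pl)) data.frame(person = pl$person,
                             site_row = match(labs$site_id[pl$lab], sites$site_id))
  )
  dup <- stats::runif(nrow(emr)) < config$duplicate_emr_rate
  emr <- rbind(emr, emr[dup, , drop = FALSE])
  emr <- emr[order(emr$person, emr$site_row), , drop = FALSE]
  m <- nrow(emr)
  emr$record_id <- sprintf("r%07d", seq_len(m))

  # ---- per-EMR corruption ----------------------------------------------
  p <- persons[emr$person, , drop = FALSE]
  s <- sites[emr$site_row, , drop = FALSE]
  first <- p$first_name
  last <- p$last_name
  bday <- p$birth_day
  bmon <- p$birth_month
  byr <- p$birth_year
  medicare <- p$medicare_number

  medicare[stats::runif(m) < s$medicare_missing_rate] <- NA_character_

  nick_hit <- stats::runif(m) < s$nickname_rate
  for (i in which(nick_hit)) {
    alts <- nick_rev[[first[i]]]
    if (length(alts)) first[i] <- if (length(alts) == 1L) alts else sample(alts, 1L)
  }

  typo_hit <- stats::runif(m) < s$name_typo_rate
  typo_breaks <- stats::runif(m) < config$typo_phonetic_break_prob
  typo_on_first <- stats::runif(m) < 0.5
  for (i in which(typo_hit)) {
    fn <- if (typo_breaks[i]) .typo_breaking else .typo_preserving
    if (typo_on_first[i]) first[i] <- fn(first[i]) else last[i] <- fn(last[i])
  }

  transpose_hit <- stats::runif(m) < s$dob_transpose_rate
  tmp <- bday[transpose_hit]
  bday[transpose_hit] <- bmon[transpose_hit]
  bmon[transpose_hit] <- tmp

  partial_hit <- stats::runif(m) < s$partial_dob_rate
  bday[partial_hit] <- NA_integer_
  bmon[partial_hit] <- NA_integer_

  identified <- data.frame(
    record_id = emr$record_id,
    site_id = s$site_id,
    site_type = s$site_type,
    first_name = first,
    last_name = last,
    birth_day = bday,
    birth_month = bmon,
    birth_year = byr,
    sex = p$sex,
    postcode = p$postcode,
    medicare_number = medicare,
    stringsAsFactors = FALSE
  )

  # ---- attach tests to EMRs --------------------------------------------
  emr_key <- paste(emr$person, sites$site_id[emr$site_row], sep = "|")
  emr_by_key <- split(seq_len(m), emr_key)
  pick_emr <- function(person, site_id) {
    rows <- emr_by_key[[paste(person, site_id, sep = "|")]]
    if (length(rows) == 1L) rows else sample(rows, 1L)
  }

  serology <- function(pidx, date) {
    # result per analyte for one event at one person/date
    hiv_pos <- persons$hiv_positive[pidx] &
      date >= persons$hiv_infection_date[pidx]
    hcv_pos <- persons$hcv_positive[pidx] &
      date >= persons$hcv_infection_date[pidx]
    data.frame(
      analyte = c("HIV_AB", "HCV_AB"),
      result = c(ifelse(hiv_pos, "positive", "negative"),
                 ifelse(hcv_pos, "positive", "negative")),
      stringsAsFactors = FALSE
    )
  }

  test_rows <- vector("list", n_ev * 2L)
  k <- 0L
  first_hiv_pos_seen <- logical(n)
  ord <- order(ev_person, ev_date)
  for (e in ord) {
    pidx <- ev_person[e]
    cl_site <- clinics$site_id[ev_clinic[e]]
    cl_emr <- emr$record_id[pick_emr(pidx, cl_site)]
    sero <- serology(pidx, ev_date[e])
    # confirmatory western blot accompanies the first positive HIV antibody
    if (any(sero$analyte == "HIV_AB" & sero$result == "positive") &&
        !first_hiv_pos_seen[pidx]) {
      sero <- rbind(sero, data.frame(analyte = "HIV_WB", result = "positive",
                                     stringsAsFactors = FALSE))
      first_hiv_pos_seen[pidx] <- TRUE
    }
    clinic_rows <- data.frame(record_id = cl_emr, analyte = sero$analyte,
                              result = sero$result, test_date = ev_date[e],
                              specimen_id = ev_specimen[e],
                              stringsAsFactors = FALSE)
    k <- k + 1L
    test_rows[[k]] <- clinic_rows
    if (!is.na(ev_lab[e])) {
      lab_site <- labs$site_id[ev_lab[e]]
      lab_emr <- emr$record_id[pick_emr(pidx, lab_site)]
      # a jittered lab date must not carry a pre-infection negative past the
      # infection date, or a negative result would post-date a positive one
      jit <- ev_jitter[e]
      if (jit > 0L) {
        crosses <- function(inf, neg) {
          !is.na(inf) && neg && inf > ev_date[e] && inf <= ev_date[e] + jit
        }
        if (crosses(persons$hiv_infection_date[pidx],
                    any(sero$analyte == "HIV_AB" & sero$result == "negative")) ||
            crosses(persons$hcv_infection_date[pidx],
                    any(sero$analyte == "HCV_AB" & sero$result == "negative"))) {
          jit <- 0L
        }
      }
      lab_rows <- clinic_rows
      lab_rows$record_id <- lab_emr
      lab_rows$test_date <- ev_date[e] + jit
      k <- k + 1L
      test_rows[[k]] <- lab_rows
    }
  }
  tests <- if (k > 0L) do.call(rbind, test_rows[seq_len(k)]) else
    data.frame(record_id = character(0), analyte = character(0),
               result = character(0), test_date = as.Date(character(0)),
               specimen_id = character(0), stringsAsFactors = FALSE)
  tests <- tests[order(tests$record_id, tests$test_date, tests$analyte), ,
                 drop = FALSE]
  rownames(tests) <- NULL

  truth <- data.frame(record_id = emr$record_id,
                      person_id = persons$person_id[emr$person],
                      stringsAsFactors = FALSE)
  registry <- data.frame(person_id = truth$person_id,
                         record_id = truth$record_id,
                         stringsAsFactors = FALSE)

  list(identified = identified, truth = truth, tests = tests,
       registry = registry, persons = persons, config = config)
}

#' Inject false links into a clustering
#'
#' Perturbs a ground-truth clustering by unioning randomly chosen
#' cross-cluster record pairs, for testing the discordance audit and the
#' specificity estimator against a known false-link rate. Each record of
#' `eligible_a` independently acquires, with probability `rate`, a link to a
#' random record drawn from `eligible_b` belonging to a different cluster.
#'
#' @param clusters Named character vector `record_id -> cluster_id` (e.g.
#'   built from the truth table).
#' @param rate False-link probability per eligible record, in `[0, 0.5]`.
#' @param eligible_a Records that may acquire a false link (default: all).
#' @param eligible_b Records a false link may attach to (default: all).
#' @return A list with `clusters` (the perturbed named vector, labelled by
#'   smallest member) and `injected_pairs` (data.frame `record_id_a`,
#'   `record_id_b`).
#' @export
inject_false_links <- function(clusters, rate, eligible_a = NULL,
                               eligible_b = NULL) {
  stopifnot(rate >= 0, rate <= 0.5)
  ids <- names(clusters)
  eligible_a <- eligible_a %||% ids
  eligible_b <- eligible_b %||% ids
  stopifnot(all(eligible_a %in% ids), all(eligible_b %in% ids))

  chosen <- eligible_a[stats::runif(length(eligible_a)) < rate]
  pa <- character(0); pb <- character(0)
  for (a in chosen) {
    pool <- eligible_b[clusters[eligible_b] != clusters[a] & eligible_b != a]
    if (!length(pool)) next
    b <- if (length(pool) == 1L) pool else sample(pool, 1L)
    pa <- c(pa, a); pb <- c(pb, b)
  }
  # union: edges within original clusters plus the injected pairs
  reps <- tapply(ids, clusters, function(v) v[1L])
  base_edges <- cbind(ids, unname(reps[clusters]))
  base_edges <- base_edges[base_edges[, 1L] != base_edges[, 2L], , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = sort(ids))
  edges <- rbind(base_edges, cbind(pa, pb))
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  comp <- igraph::components(g)$membership
  lab <- tapply(names(comp), comp, min)
  out <- stats::setNames(as.character(lab[as.character(comp)]), names(comp))
  list(clusters = out[ids],
       injected_pairs = data.frame(record_id_a = pa, record_id_b = pb,
                                   stringsAsFactors = FALSE))
}
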