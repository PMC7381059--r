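# Linkage-quality evaluation: gold-standard builders, record-level
# sensitivity / specificity / PPV / NPV, the discordant-serology audit, and
# specificity estimation from PPV and sensitivity.

new_gold_standard <- function(clusters) {
  sizes <- table(clusters)
  linked <- names(clusters)[clusters %in% names(sizes)[sizes >= 2]]
  structure(list(clusters = clusters,
                 linked_ids = linked,
                 unlinked_ids = setdiff(names(clusters), linked)),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard>", length(x$clusters), "records,",
      length(x$linked_ids), "linked,", length(x$unlinked_ids), "unlinked\n")
  invisible(x)
}

#' Gold standard from an auxiliary person registry
#'
#' Records sharing an auxiliary person ID (e.g. a study enrolment ID recorded
#' alongside the clinic medical-record number) form one gold cluster; every
#' other record is a gold singleton.
#'
#' @param records Data.frame with a `record_id` column: the full record set
#'   under evaluation.
#' @param registry Data.frame with columns `person_id`, `record_id`. A record
#'   listed under two different person IDs is a registry conflict and an
#'   error.
#' @return A `gold_standard` object: `clusters` (named vector
#'   `record_id -> gold_id`), `linked_ids` (records in clusters of size >= 2)
#'   and `unlinked_ids` (singletons).
#' @export
build_gold_registry <- function(records, registry) {
  ids <- as.character(records$record_id)
  if (anyDuplicated(ids)) stop("duplicate record_id in records")
  reg <- unique(data.frame(person_id = as.character(registry$person_id),
                           record_id = as.character(registry$record_id),
                           stringsAsFactors = FALSE))
  if (!all(reg$record_id %in% ids)) {
    stop("registry references record IDs absent from the record set")
  }
  if (anyDuplicated(reg$record_id)) {
    stop("registry conflict: a record is assigned to two person IDs")
  }
  gold <- stats::setNames(ids, ids)  # default: own singleton
  hit <- match(ids, reg$record_id)
  gold[!is.na(hit)] <- reg$person_id[hit[!is.na(hit)]]
  new_gold_standard(gold)
}

#' Gold standard from clinic-laboratory specimen flows
#'
#' A clinic record and a laboratory record are gold-matched iff they carry
#' the same laboratory specimen ID, the same year of birth, and test dates at
#' most `date_tolerance_days` apart (inclusive; recorded dates for one
#' specimen commonly differ by a few days). Matches are unioned transitively
#' into clusters. Only matched records enter the gold standard: an unmatched
#' specimen cannot be verified to belong to a distinct person, so such
#' records are excluded rather than called unlinked.
#'
#' @param clinic_tests,lab_tests Data.frames with columns `record_id`,
#'   `specimen_id`, `test_date` (Date or ISO string).
#' @param records Data.frame with `record_id`, `birth_year` covering both
#'   test tables.
#' @param date_tolerance_days Maximum date difference in days (default 7).
#' @return A `gold_standard` whose records all belong to clusters of size
#'   >= 2 (`unlinked_ids` is empty).
#' @export
build_gold_specimen <- function(clinic_tests, lab_tests, records,
                                date_tolerance_days = 7) {
  yob <- stats::setNames(records$birth_year, as.character(records$record_id))
  prep <- function(x) {
    data.frame(record_id = as.character(x$record_id),
               specimen_id = as.character(x$specimen_id),
               test_date = as.Date(x$test_date),
               stringsAsFactors = FALSE)
  }
  ct <- prep(clinic_tests)
  lt <- prep(lab_tests)
  ct <- ct[!is.na(ct$specimen_id), ]
  lt <- lt[!is.na(lt$specimen_id), ]
  m <- merge(ct, lt, by = "specimen_id", suffixes = c("_clinic", "_lab"))
  if (nrow(m)) {
    ya <- yob[m$record_id_clinic]
    yb <- yob[m$record_id_lab]
    dd <- abs(as.numeric(m$test_date_clinic - m$test_date_lab))
    keep <- !is.na(ya) & !is.na(yb) & ya == yb & dd <= date_tolerance_days
    m <- m[keep, , drop = FALSE]
  }
  if (!nrow(m)) return(new_gold_standard(stats::setNames(character(0), character(0))))
  verts <- sort(unique(c(m$record_id_clinic, m$record_id_lab)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  g <- igraph::add_edges(g, as.vector(rbind(m$record_id_clinic, m$record_id_lab)))
  comp <- igraph::components(g)$membership
  lab <- tapply(names(comp), comp, min)
  new_gold_standard(stats::setNames(as.character(lab[as.character(comp)]),
                                    names(comp)))
}

#' Score a linkage result against a gold standard
#'
#' Record-level scoring. A gold-linked record is *correctly linked* iff the
#' tool places it in one cluster with at least one member of its gold cluster
#' (set `all_comembers = TRUE` for the stricter definition requiring all of
#' them). A gold-unlinked record is *correctly unlinked* iff the tool links
#' it to no other record of the evaluated set. Then
#' * sensitivity = correctly linked / gold-linked,
#' * specificity = correctly unlinked / gold-unlinked,
#' * PPV = fraction of tool-linked records that are gold-linked and correctly
#'   linked,
#' * NPV = fraction of tool-unlinked records that are gold-unlinked.
#'
#' Percentages are rounded half-up to two decimals; a metric with an empty
#' denominator (e.g. specificity when the gold standard has no singletons) is
#' `NA`.
#'
#' @param result A `linkage_result` covering at least the gold record set.
#' @param gold A `gold_standard`.
#' @param all_comembers Use the stricter all-co-members definition of
#'   correctly linked (default `FALSE`).
#' @return A `linkage_eval` object (also a one-row data.frame) with counts
#'   and percentages.
#' @export
score_linkage <- function(result, gold, all_comembers = FALSE) {
  stopifnot(inherits(result, "linkage_result"), inherits(gold, "gold_standard"))
  ids <- names(gold$clusters)
  if (!all(ids %in% names(result$clusters))) {
    missing_n <- sum(!(ids %in% names(result$clusters)))
    stop("linkage result does not cover the gold record set (",
         missing_n, " records missing)")
  }
  tool <- result$clusters[ids]
  gold_cl <- gold$clusters

  tool_sizes <- table(tool)
  tool_linked <- unname(tool_sizes[tool] >= 2)

  # correctly linked: shares tool cluster with >= 1 (or all) gold co-members
  combo <- paste(tool, gold_cl[ids], sep = "\x1f")
  combo_n <- table(combo)
  n_same <- unname(combo_n[combo]) - 1L      # gold co-members in same tool cluster
  gold_sizes <- table(gold_cl)
  n_gold_co <- unname(gold_sizes[gold_cl[ids]]) - 1L
  is_gold_linked <- ids %in% gold$linked_ids
  correctly_linked <- if (all_comembers) {
    is_gold_linked & n_same == n_gold_co
  } else {
    is_gold_linked & n_same >= 1L
  }
  correctly_unlinked <- !is_gold_linked & !tool_linked

  n_gold_linked <- sum(is_gold_linked)
  n_gold_unlinked <- sum(!is_gold_linked)
  n_tool_linked <- sum(tool_linked)
  n_tool_unlinked <- sum(!tool_linked)

  out <- data.frame(
    approach = result$approach,
    n_gold_linked = n_gold_linked,
    n_correctly_linked = sum(correctly_linked),
    sensitivity_pct = pct(sum(correctly_linked), n_gold_linked),
    n_gold_unlinked = n_gold_unlinked,
    n_correctly_unlinked = sum(correctly_unlinked),
    specificity_pct = pct(sum(correctly_unlinked), n_gold_unlinked),
    n_tool_linked = n_tool_linked,
    n_tool_linked_correct = sum(tool_linked & correctly_linked),
    ppv_pct = pct(sum(tool_linked & correctly_linked), n_tool_linked),
    n_tool_unlinked = n_tool_unlinked,
    n_tool_unlinked_correct = sum(!tool_linked & !is_gold_linked),
    npv_pct = pct(sum(!tool_linked & !is_gold_linked), n_tool_unlinked),
    stringsAsFactors = FALSE
  )
  class(out) <- c("linkage_eval", class(out))
  out
}

# analyte sets per audited infection class
.analyte_spec <- function(analyte_class) {
  switch(analyte_class,
    HIV = list(relevant = c("HIV_WB", "HIV_AB"), antibody = "HIV_AB",
               initial = "HIV_WB"),
    HCV = list(relevant = "HCV_AB", antibody = "HCV_AB", initial = "HCV_AB"),
    stop("unknown analyte class: ", analyte_class)
  )
}

#' Discordant-serology audit of a linkage result
#'
#' After infection, HIV and hepatitis C antibody tests remain positive, so a
#' negative antibody result at least `window_days` after a positive result
#' within one linked cluster is biologically impossible for a single person
#' and marks a wrong link. The audit, in order:
#'
#' 1. excludes records whose *own* test history is already discordant before
#'    linkage (so pre-existing data errors are not attributed to linkage);
#' 2. retains linked clusters that contain an antibody result dated after the
#'    cluster's initial positive (HIV: initial positive western blot; HCV:
#'    initial positive antibody) — discordance is only determinable after an
#'    initial positive;
#' 3. classifies a cluster discordant if any negative antibody occurs at
#'    least `window_days` after a positive result in the cluster;
#' 4. attributes the wrong records: if a strict majority of the antibody
#'    results after the initial positive are negative, the records
#'    contributing positive results are taken to be the intruders; otherwise
#'    the records contributing the discordant negatives are.
#'
#' PPV is the fraction of retained records not attributed as wrong.
#'
#' @param result A `linkage_result`.
#' @param tests Data.frame with columns `record_id`, `analyte` (one of
#'   `HIV_WB`, `HIV_AB`, `HCV_AB`), `result` (`"positive"`/`"negative"`),
#'   `test_date` (Date or ISO string).
#' @param analyte_class `"HIV"` or `"HCV"`.
#' @param window_days Discordance window in days (default 7).
#' @return A `serology_audit` object: `approach`, `analyte_class`,
#'   `n_excluded_pre`, `n_linked_with_initial_positive` (retained records),
#'   `n_concordant`, `ppv_pct`, `retained_ids` (the audited record set), and
#'   `flagged` (data.frame of discordant clusters: `link_id`, `record_id`,
#'   `attributed_wrong`).
#' @export
serology_audit <- function(result, tests, analyte_class = c("HIV", "HCV"),
                           window_days = 7) {
  stopifnot(inherits(result, "linkage_result"))
  analyte_class <- match.arg(analyte_class)
  spec <- .analyte_spec(analyte_class)

  tt <- data.frame(record_id = as.character(tests$record_id),
                   analyte = as.character(tests$analyte),
                   result = as.character(tests$result),
                   test_date = as.Date(tests$test_date),
                   stringsAsFactors = FALSE)
  tt <- tt[tt$analyte %in% spec$relevant, , drop = FALSE]
  pos <- tt[tt$result == "positive", , drop = FALSE]
  neg_ab <- tt[tt$result == "negative" & tt$analyte == spec$antibody, ,
               drop = FALSE]

  # step 1: records internally discordant before linkage
  discordant_record <- function(rids_pos, dates_pos, rids_neg, dates_neg) {
    # for each record, is there a negative >= window after a positive?
    out <- character(0)
    for (r in intersect(unique(rids_pos), unique(rids_neg))) {
      p <- dates_pos[rids_pos == r]
      q <- dates_neg[rids_neg == r]
      if (length(p) && length(q) &&
          max(q) - min(p) >= window_days &&
          any(outer(as.numeric(q), as.numeric(p), "-") >= window_days)) {
        out <- c(out, r)
      }
    }
    out
  }
  excluded <- discordant_record(pos$record_id, pos$test_date,
                                neg_ab$record_id, neg_ab$test_date)

  keep_ids <- setdiff(names(result$clusters), excluded)
  clusters <- result$clusters[keep_ids]
  tt <- tt[tt$record_id %in% keep_ids, , drop = FALSE]
  tt$link_id <- unname(clusters[tt$record_id])

  sizes <- table(clusters)
  linked_ids <- names(clusters)[clusters %in% names(sizes)[sizes >= 2]]
  lt <- tt[tt$record_id %in% linked_ids, , drop = FALSE]

  # step 2: retained clusters have an initial positive and a later antibody
  flagged <- data.frame(link_id = character(0), record_id = character(0),
                        attributed_wrong = logical(0), stringsAsFactors = FALSE)
  retained_clusters <- character(0)
  wrong_records <- character(0)
  by_cluster <- split(lt, lt$link_id)
  for (cl in names(by_cluster)) {
    sub <- by_cluster[[cl]]
    ini <- sub[sub$analyte == spec$initial & sub$result == "positive", ,
               drop = FALSE]
    if (!nrow(ini)) next
    t0 <- min(ini$test_date)
    after_ab <- sub[sub$analyte == spec$antibody & sub$test_date > t0, ,
                    drop = FALSE]
    if (!nrow(after_ab)) next
    retained_clusters <- c(retained_clusters, cl)

    # step 3: discordance within the merged cluster history
    sub_pos <- sub[sub$result == "positive", , drop = FALSE]
    sub_neg <- after_ab[after_ab$result == "negative", , drop = FALSE]
    gaps <- if (nrow(sub_neg) && nrow(sub_pos)) {
      outer(as.numeric(sub_neg$test_date), as.numeric(sub_pos$test_date), "-")
    } else {
      matrix(numeric(0), nrow = nrow(sub_neg))
    }
    neg_discordant <- nrow(sub_neg) > 0 && nrow(sub_pos) > 0 &&
      any(gaps >= window_days)
    if (!neg_discordant) next

    # step 4: attribute the intruding records
    n_neg_after <- sum(after_ab$result == "negative")
    n_after <- nrow(after_ab)
    if (n_neg_after * 2L > n_after) {
      wrong <- unique(sub_pos$record_id)
    } else {
      which_disc <- rowSums(gaps >= window_days) > 0
      wrong <- unique(sub_neg$record_id[which_disc])
    }
    wrong_records <- c(wrong_records, wrong)
    members <- names(clusters)[clusters == cl]
    flagged <- rbind(flagged,
                     data.frame(link_id = cl, record_id = members,
                                attributed_wrong = members %in% wrong,
                                stringsAsFactors = FALSE))
  }

  retained_ids <- names(clusters)[clusters %in% retained_clusters]
  n_retained <- length(retained_ids)
  n_wrong <- length(intersect(retained_ids, wrong_records))
  structure(list(
    approach = result$approach,
    analyte_class = analyte_class,
    window_days = window_days,
    n_excluded_pre = length(excluded),
    n_linked_with_initial_positive = n_retained,
    n_concordant = n_retained - n_wrong,
    ppv_pct = pct(n_retained - n_wrong, n_retained),
    retained_ids = retained_ids,
    flagged = flagged
  ), class = "serology_audit")
}

#' @export
print.serology_audit <- function(x, ...) {
  cat("<serology_audit>", x$analyte_class, "approach:", x$approach,
      "\n  retained records:", x$n_linked_with_initial_positive,
      " concordant:", x$n_concordant,
      " PPV:", ifelse(is.na(x$ppv_pct), "not estimable",
                      paste0(x$ppv_pct, "%")), "\n")
  invisible(x)
}

#' Estimate specificity from PPV, sensitivity and prevalence
#'
#' Inverts the Bayes identity
#' `PPV = Se * pi / (Se * pi + (1 - Sp) * (1 - pi))`
#' to `Sp = 1 - Se * pi * (1 - PPV) / (PPV * (1 - pi))`, where `pi` is the
#' prevalence of truly-linked records. Used when specificity cannot be
#' measured directly (no verified singletons) but PPV is available from the
#' serology audit and sensitivity from a gold standard.
#'
#' @param ppv,sensitivity Proportions in `(0, 1]`.
#' @param prevalence Proportion in `(0, 1)`: fraction of records that are
#'   truly linked.
#' @return Estimated specificity as a proportion, clamped to `[0, 1]`.
#' @examples
#' estimate_specificity(1, 1, 0.3)  # 1: perfect linkage
#' @export
estimate_specificity <- function(ppv, sensitivity, prevalence) {
  if (!is.finite(ppv) || ppv <= 0 || ppv > 1) {
    stop("ppv must be in (0, 1]")
  }
  if (!is.finite(sensitivity) || sensitivity <= 0 || sensitivity > 1) {
    stop("sensitivity must be in (0, 1]")
  }
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be in (0, 1)")
  }
  sp <- 1 - sensitivity * prevalence * (1 - ppv) / (ppv * (1 - prevalence))
  min(max(sp, 0), 1)
}
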