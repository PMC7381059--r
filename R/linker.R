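# The three-step linkage process: (1) candidate pairs from exact key-value
# matches found with an inverted index per key type, (2) acceptance of pairs
# under a configurable approach, (3) link-ID assignment by transitive closure
# of the accepted pairs. No similarity joins are needed because all fuzziness
# was applied before hashing.

#' Names of the supported match-acceptance approaches
#' @return Character vector of the six approach names.
#' @export
linkage_approaches <- function() {
  c("accept_all", "yob_match", "sex_match", "yob_sex_match",
    "two_or_more_keys", "key3_plus_sex")
}

#' Find candidate record pairs by linkage-key matching
#'
#' A pair of records is a candidate iff at least one key type is present on
#' both and equal; the complete set of matching key types is recorded for
#' each pair. Implemented with an inverted index per key type (records
#' grouped by key value), never by all-pairs comparison, but the output is
#' identical to the brute-force definition.
#'
#' @param records Deidentified records data.frame with columns `record_id`,
#'   `key1`..`key4`. Record IDs must be unique.
#' @return A data.frame of pairs: `record_id_a`, `record_id_b` (with
#'   `a < b` in string order) and `matched_types` (e.g. `"1;3;4"`).
#' @export
find_candidate_pairs <- function(records) {
  ids <- as.character(records$record_id)
  if (anyDuplicated(ids)) stop("duplicate record_id in input records")
  n <- length(ids)
  pair_i <- integer(0); pair_j <- integer(0); pair_t <- integer(0)
  for (t in 1:4) {
    key <- records[[paste0("key", t)]]
    ok <- which(!is.na(key))
    if (!length(ok)) next
    groups <- split(ok, key[ok])
    groups <- groups[lengths(groups) >= 2L]
    for (g in groups) {
      cmb <- utils::combn(g, 2L)
      pair_i <- c(pair_i, cmb[1L, ])
      pair_j <- c(pair_j, cmb[2L, ])
      pair_t <- c(pair_t, rep.int(t, ncol(cmb)))
    }
  }
  if (!length(pair_i)) {
    return(data.frame(record_id_a = character(0), record_id_b = character(0),
                      matched_types = character(0), stringsAsFactors = FALSE))
  }
  a <- pmin(ids[pair_i], ids[pair_j])
  b <- pmax(ids[pair_i], ids[pair_j])
  pair_key <- paste(a, b, sep = "\x1f")
  ord <- order(pair_key, pair_t)
  pair_key <- pair_key[ord]; a <- a[ord]; b <- b[ord]; pair_t <- pair_t[ord]
  first <- !duplicated(pair_key)
  types <- vapply(split(pair_t, factor(pair_key, levels = pair_key[first])),
                  function(x) paste(sort(unique(x)), collapse = ";"),
                  character(1))
  data.frame(record_id_a = a[first], record_id_b = b[first],
             matched_types = unname(types), stringsAsFactors = FALSE)
}

# does the ";"-encoded type set contain type t?
pair_has_type <- function(matched_types, t) {
  vapply(strsplit(matched_types, ";", fixed = TRUE),
         function(x) as.character(t) %in% x, logical(1))
}

n_matched_types <- function(matched_types) {
  lengths(strsplit(matched_types, ";", fixed = TRUE))
}

#' Accept or reject candidate pairs under a linkage approach
#'
#' The six approaches: accept every candidate pair (`accept_all`); require
#' equal year of birth (`yob_match`); equal sex (`sex_match`); both
#' (`yob_sex_match`); at least two matching key types
#' (`two_or_more_keys`); or a key-type-3 match together with equal sex
#' (`key3_plus_sex`).
#'
#' @param pairs Candidate pairs from [find_candidate_pairs()].
#' @param records Deidentified records with `record_id`, `sex`,
#'   `birth_year`.
#' @param approach One of [linkage_approaches()].
#' @param strict_missing With the default `TRUE`, a missing sex or birth
#'   year on either side fails the corresponding comparison (favouring
#'   specificity); with `FALSE` a missing value is treated as compatible.
#' @return The subset of `pairs` accepted by the approach.
#' @export
accept_pairs <- function(pairs, records, approach = linkage_approaches(),
                         strict_missing = TRUE) {
  approach <- match.arg(approach)
  if (!nrow(pairs)) return(pairs)
  ia <- match(pairs$record_id_a, records$record_id)
  ib <- match(pairs$record_id_b, records$record_id)
  if (anyNA(ia) || anyNA(ib)) stop("pairs reference unknown record IDs")

  field_equal <- function(col) {
    va <- records[[col]][ia]
    vb <- records[[col]][ib]
    eq <- !is.na(va) & !is.na(vb) & va == vb
    if (!strict_missing) eq <- eq | is.na(va) | is.na(vb)
    eq
  }
  keep <- switch(approach,
    accept_all = rep(TRUE, nrow(pairs)),
    yob_match = field_equal("birth_year"),
    sex_match = field_equal("sex"),
    yob_sex_match = field_equal("birth_year") & field_equal("sex"),
    two_or_more_keys = n_matched_types(pairs$matched_types) >= 2L,
    key3_plus_sex = pair_has_type(pairs$matched_types, 3L) & field_equal("sex")
  )
  pairs[keep, , drop = FALSE]
}

#' Assign link IDs by transitive closure of accepted pairs
#'
#' Link IDs are the connected components of the accepted-pair graph; every
#' record, including singletons, receives a link ID. Components are labelled
#' by their smallest member record ID, which makes the labelling independent
#' of input order.
#'
#' @param records Deidentified records (`record_id` column used).
#' @param accepted_pairs Accepted pairs (from [accept_pairs()]).
#' @param approach Approach name stored in the result, for reporting.
#' @return An object of class `linkage_result`: list with `clusters` (named
#'   character vector, `record_id -> link_id`), `accepted_pairs`, and
#'   `approach`.
#' @export
assign_link_ids <- function(records, accepted_pairs, approach = NA_character_) {
  ids <- sort(as.character(records$record_id))
  if (anyDuplicated(ids)) stop("duplicate record_id in input records")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  if (nrow(accepted_pairs)) {
    edges <- rbind(accepted_pairs$record_id_a, accepted_pairs$record_id_b)
    if (!all(c(accepted_pairs$record_id_a, accepted_pairs$record_id_b) %in% ids)) {
      stop("accepted pairs reference unknown record IDs")
    }
    g <- igraph::add_edges(g, as.vector(edges))
  }
  comp <- igraph::components(g)$membership
  # label each component by its smallest member; vertices were added sorted,
  # so the first vertex seen in each component is its minimum
  link_of_comp <- tapply(names(comp), comp, min)
  clusters <- stats::setNames(as.character(link_of_comp[as.character(comp)]),
                              names(comp))
  structure(list(clusters = clusters,
                 accepted_pairs = accepted_pairs,
                 approach = approach),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  sizes <- table(x$clusters)
  cat("<linkage_result>", x$approach, "-", length(x$clusters), "records,",
      sum(sizes >= 2), "clusters of size >= 2,",
      nrow(x$accepted_pairs), "accepted pairs\n")
  invisible(x)
}

#' Run the full three-step linkage
#'
#' Convenience wrapper: find candidate pairs, filter them under an approach,
#' assign link IDs.
#'
#' @inheritParams accept_pairs
#' @param records Deidentified records data.frame.
#' @return A `linkage_result`; see [assign_link_ids()].
#' @export
link_records <- function(records, approach = linkage_approaches(),
                         strict_missing = TRUE) {
  approach <- match.arg(approach)
  pairs <- find_candidate_pairs(records)
  accepted <- accept_pairs(pairs, records, approach, strict_missing)
  assign_link_ids(records, accepted, approach)
}
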