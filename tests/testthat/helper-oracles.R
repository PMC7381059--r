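# Independent brute-force oracles used to validate the indexed/graph-based
# implementations. Deliberately simple and quadratic.

# all-pairs candidate search: every record pair is compared on every key type
# (the inner comparison is vectorized over j, but all n*(n-1)/2 pairs are
# enumerated explicitly)
brute_force_pairs <- function(records) {
  ids <- as.character(records$record_id)
  n <- length(ids)
  keys <- lapply(1:4, function(t) records[[paste0("key", t)]])
  rows <- list()
  for (i in seq_len(max(n - 1, 0))) {
    js <- seq(i + 1, n)
    tm <- vapply(1:4, function(t) {
      a <- keys[[t]][i]; b <- keys[[t]][js]
      !is.na(a) & !is.na(b) & a == b
    }, logical(length(js)))
    tm <- matrix(tm, nrow = length(js))
    for (h in which(rowSums(tm) > 0)) {
      j <- js[h]
      rows[[length(rows) + 1]] <- data.frame(
        record_id_a = min(ids[i], ids[j]),
        record_id_b = max(ids[i], ids[j]),
        matched_types = paste(which(tm[h, ]), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(record_id_a = character(0), record_id_b = character(0),
                      matched_types = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$record_id_a, out$record_id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# plain union-find connected components, labelled by smallest member
union_find_components <- function(ids, pairs) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs$record_id_a[k]); rb <- find(pairs$record_id_b[k])
      if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
    }
  }
  vapply(ids, find, character(1))
}

# enumeration-based scorer: walks every record and counts the four cells
# directly from the two clusterings
brute_force_score <- function(tool_clusters, gold_clusters) {
  ids <- names(gold_clusters)
  tool <- tool_clusters[ids]
  stats_row <- c(gold_linked = 0, correctly_linked = 0, gold_unlinked = 0,
                 correctly_unlinked = 0, tool_linked = 0,
                 tool_linked_correct = 0, tool_unlinked = 0,
                 tool_unlinked_correct = 0)
  for (r in ids) {
    gold_co <- setdiff(ids[gold_clusters[ids] == gold_clusters[[r]]], r)
    tool_co <- setdiff(ids[tool == tool[[r]]], r)
    g_linked <- length(gold_co) > 0
    t_linked <- length(tool_co) > 0
    correct_link <- g_linked && length(intersect(gold_co, tool_co)) > 0
    if (g_linked) {
      stats_row["gold_linked"] <- stats_row["gold_linked"] + 1
      if (correct_link) stats_row["correctly_linked"] <- stats_row["correctly_linked"] + 1
    } else {
      stats_row["gold_unlinked"] <- stats_row["gold_unlinked"] + 1
      if (!t_linked) stats_row["correctly_unlinked"] <- stats_row["correctly_unlinked"] + 1
    }
    if (t_linked) {
      stats_row["tool_linked"] <- stats_row["tool_linked"] + 1
      if (correct_link) stats_row["tool_linked_correct"] <- stats_row["tool_linked_correct"] + 1
    } else {
      stats_row["tool_unlinked"] <- stats_row["tool_unlinked"] + 1
      if (!g_linked) stats_row["tool_unlinked_correct"] <- stats_row["tool_unlinked_correct"] + 1
    }
  }
  as.list(stats_row)
}

# random deidentified table: keys drawn from tiny alphabets so collisions and
# multi-type matches are common; NA rate controls missingness
random_deid <- function(n, seed, key_space = 12, na_rate = 0.3) {
  set.seed(seed)
  df <- data.frame(record_id = sprintf("r%04d", sample(n * 10, n)),
                   stringsAsFactors = FALSE)
  for (t in 1:4) {
    k <- sprintf("v%d_%d", t, sample.int(key_space, n, replace = TRUE))
    k[stats::runif(n) < na_rate] <- NA_character_
    df[[paste0("key", t)]] <- k
  }
  df$sex <- sample(c("M", "F", NA), n, replace = TRUE)
  df$birth_year <- sample(c(1960:1990, NA), n, replace = TRUE)
  df
}

# linkage result built directly from a record_id -> cluster_id vector
as_result <- function(clusters, approach = "truth") {
  structure(list(clusters = clusters, accepted_pairs = data.frame(),
                 approach = approach),
            class = "linkage_result")
}

# gold standard built directly from a record_id -> gold_id vector
as_gold <- function(clusters) {
  build_gold_registry(
    data.frame(record_id = names(clusters), stringsAsFactors = FALSE),
    data.frame(person_id = unname(clusters), record_id = names(clusters),
               stringsAsFactors = FALSE))
}

# a complete raw identity row; fields overridable per test
raw_identity <- function(record_id = "r1", site_id = "clinic1",
                         site_type = "clinic", first_name = "William",
                         last_name = "Smith", birth_day = 3, birth_month = 5,
                         birth_year = 1990, sex = "M", postcode = "3000",
                         medicare_number = "2123456701") {
  data.frame(record_id = record_id, site_id = site_id, site_type = site_type,
             first_name = first_name, last_name = last_name,
             birth_day = birth_day, birth_month = birth_month,
             birth_year = birth_year, sex = sex, postcode = postcode,
             medicare_number = medicare_number, stringsAsFactors = FALSE)
}

test_keygen_config <- function() keygen_config("unit-test-secret", 32)
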