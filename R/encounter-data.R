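#' Assemble an encounter-history dataset
#'
#' Bundles individual binary detection histories, age-at-first-breeding group
#' labels and an optional per-occasion environmental covariate into the tibble
#' that all downstream operations (goodness-of-fit tests, transient-CJS
#' fitting, m-array reduction) consume. Occasions are annual and ordered; the
#' first detection in a history defines the individual's release (first
#' breeding) occasion.
#'
#' @param histories Character vector of 0/1 strings (one per individual, all
#'   the same length), or a 0/1 integer matrix with one row per individual.
#' @param group Age-at-first-breeding class per individual; one of
#'   `"3", "4", "5", "6", "7plus"`.
#' @param id Optional individual identifiers; generated when missing.
#' @param occasions Optional occasion labels (e.g. years); defaults to
#'   `"t1" ... "tK"`.
#' @param covariate Optional numeric per-occasion covariate (a
#'   density-dependence proxy such as food per capita); length must equal the
#'   number of occasions.
#'
#' @return A tibble of class `encounter_df` with columns `id`, `group` and
#'   `history`, carrying `occasions` and `covariate` attributes.
#' @export
#' @examples
#' encounter_data(c("1011", "0101"), group = c("3", "4"))
encounter_data <- function(histories, group, id = NULL, occasions = NULL,
                           covariate = NULL) {
  if (is.matrix(histories)) {
    histories <- apply(histories, 1L, paste, collapse = "")
  }
  histories <- as.character(histories)
  n <- length(histories)
  if (n == 0L) abort("no encounter histories supplied")
  len <- unique(nchar(histories))
  if (length(len) != 1L) abort("all histories must have the same length")
  if (any(grepl("[^01]", histories))) {
    abort("histories may only contain the characters 0 and 1")
  }
  if (any(!grepl("1", histories))) {
    abort("every history must contain at least one detection (all-zero history found)")
  }
  if (length(group) == 1L) group <- rep(group, n)
  if (length(group) != n) abort("`group` must have one entry per individual")
  if (is.null(id)) id <- sprintf("ind%05d", seq_len(n))
  if (anyDuplicated(id)) abort("individual ids must be unique")
  occasions <- occasions %||% paste0("t", seq_len(len))
  if (length(occasions) != len) {
    abort("`occasions` must have one label per detection column")
  }
  if (!is.null(covariate)) {
    covariate <- as.numeric(covariate)
    if (length(covariate) != len) {
      abort("`covariate` must have one value per occasion")
    }
  }
  out <- tibble::tibble(
    id = as.character(id),
    group = group_factor(group),
    history = histories
  )
  attr(out, "occasions") <- as.character(occasions)
  attr(out, "covariate") <- covariate
  class(out) <- c("encounter_df", class(out))
  out
}

#' @export
print.encounter_df <- function(x, ...) {
  cat(sprintf(
    "<encounter_df> %d individuals x %d occasions%s\n",
    nrow(x), n_occasions(x),
    if (is.null(attr(x, "covariate"))) "" else " (with covariate)"
  ))
  NextMethod()
}

#' Number of occasions in an encounter dataset
#' @param data An `encounter_df`.
#' @return Integer number of sampling occasions.
#' @export
n_occasions <- function(data) {
  length(attr(data, "occasions"))
}

#' Detection histories as a 0/1 matrix
#' @param data An `encounter_df`.
#' @return Integer matrix, individuals in rows, occasions in columns.
#' @export
history_matrix <- function(data) {
  H <- do.call(rbind, lapply(strsplit(data$history, ""), as.integer))
  rownames(H) <- data$id
  colnames(H) <- attr(data, "occasions")
  H
}

#' Per-occasion covariate series attached to a dataset
#' @param data An `encounter_df`.
#' @return Numeric vector or `NULL`.
#' @export
covariate_series <- function(data) {
  attr(data, "covariate")
}

strip_inp_comments <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("/\\*.*?\\*/", "", txt, perl = TRUE)
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

#' Read encounter histories from a MARK-style .inp file
#'
#' Each record is a 0/1 history string followed by one frequency column per
#' group and a terminating semicolon. `/* ... */` comments and blank lines are
#' ignored. Frequencies are expanded so that each unit of frequency becomes
#' one individual.
#'
#' @param path Path to the `.inp` file.
#' @param group_labels Ordered labels for the frequency columns (defaults to
#'   the five age-at-first-breeding classes).
#' @param occasions,covariate Passed on to [encounter_data()].
#' @return An `encounter_df`.
#' @export
read_inp <- function(path, group_labels = GROUP_LEVELS, occasions = NULL,
                     covariate = NULL) {
  raw <- readLines(path, warn = FALSE)
  lines <- strip_inp_comments(raw)
  keep <- which(trimws(lines) != "")
  histories <- character()
  groups <- character()
  for (li in keep) {
    line <- trimws(lines[[li]])
    if (!grepl(";\\s*$", line)) {
      abort(sprintf("line %d: record does not end with ';'", li))
    }
    line <- sub(";\\s*$", "", line)
    fields <- strsplit(line, "\\s+")[[1]]
    if (length(fields) < 2L) {
      abort(sprintf("line %d: expected a history and frequency columns", li))
    }
    hist <- fields[[1]]
    freqs <- fields[-1]
    if (grepl("[^01]", hist)) {
      abort(sprintf("line %d: history contains non-binary characters", li))
    }
    if (length(freqs) != length(group_labels)) {
      abort(sprintf(
        "line %d: %d frequency columns but %d groups declared",
        li, length(freqs), length(group_labels)
      ))
    }
    freqs <- suppressWarnings(as.integer(freqs))
    if (anyNA(freqs) || any(freqs < 0)) {
      abort(sprintf("line %d: frequencies must be non-negative integers", li))
    }
    if (!grepl("1", hist) && sum(freqs) > 0) {
      abort(sprintf("line %d: all-zero history with positive frequency", li))
    }
    for (g in seq_along(freqs)) {
      if (freqs[g] > 0) {
        histories <- c(histories, rep(hist, freqs[g]))
        groups <- c(groups, rep(group_labels[g], freqs[g]))
      }
    }
  }
  lens <- unique(nchar(histories))
  if (length(lens) > 1L) {
    abort("histories in the file have inconsistent lengths")
  }
  encounter_data(histories, groups, occasions = occasions, covariate = covariate)
}

#' Write an encounter dataset in the MARK-style .inp dialect
#'
#' Identical histories within a group are collapsed into frequency counts, so
#' a write/read round trip reproduces the dataset (up to individual ids).
#'
#' @param data An `encounter_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(data, path) {
  counts <- data |>
    dplyr::count(.data$history, .data$group) |>
    tidyr::pivot_wider(
      names_from = "group", values_from = "n", values_fill = 0L,
      names_expand = TRUE
    ) |>
    dplyr::arrange(.data$history)
  freq <- as.matrix(counts[, GROUP_LEVELS, drop = FALSE])
  lines <- vapply(seq_len(nrow(counts)), function(i) {
    paste0(counts$history[i], " ", paste(freq[i, ], collapse = " "), ";")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write encounter histories as long-format CSV
#'
#' Columns `id`, `group`, `occasion`, `detected` (0/1), one row per
#' individual-occasion.
#'
#' @param path CSV path.
#' @param covariate Optional per-occasion covariate attached on read.
#' @return An `encounter_df` (read) or `path` invisibly (write).
#' @export
read_history_csv <- function(path, covariate = NULL) {
  long <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("id", "group", "occasion", "detected")
  if (!all(need %in% names(long))) {
    abort(paste0("history CSV must have columns: ", paste(need, collapse = ", ")))
  }
  occ <- unique(long$occasion)
  wide <- long |>
    dplyr::arrange(match(.data$occasion, occ)) |>
    tidyr::pivot_wider(
      id_cols = c("id", "group"),
      names_from = "occasion", values_from = "detected"
    )
  H <- as.matrix(wide[, as.character(occ), drop = FALSE])
  encounter_data(H,
    group = wide$group, id = wide$id,
    occasions = as.character(occ), covariate = covariate
  )
}

#' @rdname read_history_csv
#' @param data An `encounter_df`.
#' @export
write_history_csv <- function(data, path) {
  H <- history_matrix(data)
  long <- tibble::tibble(
    id = rep(data$id, each = ncol(H)),
    group = rep(as.character(data$group), each = ncol(H)),
    occasion = rep(colnames(H), times = nrow(H)),
    detected = as.integer(t(H))
  )
  readr::write_csv(long, path)
  invisible(path)
}

#' Re-anchor histories at the first breeding event
#'
#' Histories of animals marked before breeding age (e.g. as chicks) are
#' left-truncated so that the first retained detection is the first breeding
#' observation, and individuals are regrouped by their age at first breeding.
#' The first raw detection is taken as the birth (marking) occasion, so the
#' first breeding occasion is `birth occasion + age_at_first`. Detections from
#' that occasion onwards are kept as-is; individuals never seen breeding are
#' dropped. Ages of 7 or more are pooled into the `7plus` class.
#'
#' @param data An `encounter_df` of raw (pre-breeding inclusive) histories.
#' @param age_at_first Integer age at first breeding per individual, in the
#'   same order as `data` (or named by id). All ages must be at least 3.
#' @return An `encounter_df` of breeding-anchored histories.
#' @export
transform_to_first_breeding <- function(data, age_at_first) {
  if (!is.null(names(age_at_first))) {
    age_at_first <- age_at_first[data$id]
  }
  if (length(age_at_first) != nrow(data)) {
    abort("`age_at_first` must have one value per individual")
  }
  if (anyNA(age_at_first)) abort("`age_at_first` contains missing values")
  grp <- group_from_age(age_at_first)

  H <- history_matrix(data)
  K <- ncol(H)
  birth <- apply(H, 1L, function(h) which(h == 1L)[1L])
  first_breed <- birth + as.integer(age_at_first)
  keep <- logical(nrow(H))
  for (i in seq_len(nrow(H))) {
    if (first_breed[i] <= K) {
      H[i, seq_len(first_breed[i] - 1L)] <- 0L
      keep[i] <- any(H[i, ] == 1L)
    }
  }
  if (!any(keep)) abort("no individuals were ever seen breeding")
  encounter_data(H[keep, , drop = FALSE],
    group = grp[keep], id = data$id[keep],
    occasions = attr(data, "occasions"),
    covariate = attr(data, "covariate")
  )
}

#' Reduce encounter histories to an m-array split by time since marking
#'
#' The m-array is the sufficient statistic for CJS-type multinomial
#' likelihoods: for every release cohort (group, mark class, release occasion)
#' it records how many animals were next re-encountered at each later
#' occasion, and how many were never seen again. Animals released at their
#' first-ever detection form `newly_marked` cohorts (the cohorts that carry
#' the transience signal); re-releases after a re-encounter form
#' `previously_marked` cohorts.
#'
#' @param data An `encounter_df`.
#' @return A tibble of class `marray_df` with columns `group`, `mark_class`,
#'   `release`, `recapture` (`NA` = never seen again) and `n`, carrying the
#'   occasion count as an attribute. The conservation identity (releases =
#'   re-encounters + never-seen) holds by construction and is asserted.
#' @export
build_marray <- function(data) {
  H <- history_matrix(data)
  K <- ncol(H)
  rows <- vector("list", nrow(H))
  for (i in seq_len(nrow(H))) {
    det <- unname(which(H[i, ] == 1L))
    m <- length(det)
    cls <- c("newly_marked", rep("previously_marked", m - 1L))
    rows[[i]] <- tibble::tibble(
      group = as.character(data$group[i]),
      mark_class = cls,
      release = det,
      recapture = c(det[-1L], NA_integer_)
    )
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::count(.data$group, .data$mark_class, .data$release, .data$recapture,
      name = "n"
    ) |>
    dplyr::mutate(
      group = group_factor(.data$group),
      mark_class = factor(.data$mark_class,
        levels = c("newly_marked", "previously_marked")
      )
    ) |>
    dplyr::arrange(.data$group, .data$mark_class, .data$release, .data$recapture)
  attr(out, "n_occasions") <- K
  attr(out, "covariate") <- attr(data, "covariate")
  class(out) <- c("marray_df", class(out))
  validate_marray(out)
  out
}

#' Validate the conservation invariant of an m-array
#'
#' Checks that, for every cohort, released animals equal first re-encounters
#' plus never-seen-again, that counts are non-negative integers, and that
#' re-encounters postdate releases.
#'
#' @param marray An `marray_df`.
#' @return `marray`, invisibly; aborts on violation.
#' @export
validate_marray <- function(marray) {
  if (any(marray$n < 0) || any(marray$n != round(marray$n))) {
    abort("m-array counts must be non-negative integers")
  }
  bad <- !is.na(marray$recapture) & marray$recapture <= marray$release
  if (any(bad)) abort("re-encounters must occur strictly after release")
  # conservation: total releases at (g, class, t) equal the row sum of the
  # multinomial cells by construction of the long format; assert by recount
  rel <- marray_releases(marray)
  cells <- marray |>
    dplyr::group_by(.data$group, .data$mark_class, .data$release) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  if (!isTRUE(all.equal(rel$released[order(rel$group, rel$mark_class, rel$release)],
    cells$total[order(cells$group, cells$mark_class, cells$release)]
  ))) {
    abort("m-array conservation invariant violated")
  }
  invisible(marray)
}

#' Release totals per cohort of an m-array
#' @param marray An `marray_df`.
#' @return Tibble with `group`, `mark_class`, `release`, `released`.
#' @export
marray_releases <- function(marray) {
  marray |>
    dplyr::group_by(.data$group, .data$mark_class, .data$release) |>
    dplyr::summarise(released = sum(.data$n), .groups = "drop")
}

#' Export an m-array as a wide CSV (one row per cohort)
#'
#' @param marray An `marray_df`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marray_csv <- function(marray, path) {
  K <- attr(marray, "n_occasions")
  wide <- marray |>
    dplyr::mutate(cell = ifelse(is.na(.data$recapture), "never_seen_again",
      paste0("m_", .data$recapture)
    )) |>
    dplyr::select(-"recapture") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "n", values_fill = 0L)
  mcols <- paste0("m_", 2:K)
  for (mc in mcols) if (!mc %in% names(wide)) wide[[mc]] <- 0L
  if (!"never_seen_again" %in% names(wide)) wide$never_seen_again <- 0L
  wide <- wide[, c("group", "mark_class", "release", mcols, "never_seen_again")]
  wide$released <- rowSums(wide[, c(mcols, "never_seen_again")])
  readr::write_csv(wide, path)
  invisible(path)
}
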