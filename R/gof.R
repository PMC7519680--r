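# Pearson chi-square on a 2x2 (or r x c) table without continuity correction;
# returns NA when a margin is empty (uninformative table).
pearson_chisq <- function(tab) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, df = 0L))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(
    statistic = sum((tab - E)^2 / E),
    df = (nrow(tab) - 1L) * (ncol(tab) - 1L)
  )
}

# one occasion's contribution: Pearson when all expected cells are large
# enough, Fisher's exact test (converted to an equivalent chi-square on 1 df)
# when sparse.
table_contribution <- function(tab, sparse_threshold = 2) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, df = 0L, method = "uninformative"))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(E < sparse_threshold)) {
    pv <- fisher.test(tab)$p.value
    list(
      statistic = qchisq(max(1 - pv, 0), df = 1L),
      df = 1L, method = "fisher"
    )
  } else {
    pc <- pearson_chisq(tab)
    list(statistic = pc$statistic, df = pc$df, method = "pearson")
  }
}

new_gof_component <- function(name, per_occasion, pooled_table = NULL,
                              group = NA_character_) {
  inf <- per_occasion[per_occasion$df > 0, , drop = FALSE]
  chisq <- sum(inf$statistic)
  df <- sum(inf$df)
  undefined <- df == 0L
  z <- NA_real_
  if (!is.null(pooled_table) && !undefined) {
    pc <- pearson_chisq(pooled_table)
    if (!is.na(pc$statistic)) {
      # positive when newly encountered animals are re-seen less often than
      # previously encountered ones (the transience direction)
      E <- outer(rowSums(pooled_table), colSums(pooled_table)) / sum(pooled_table)
      direction <- sign(pooled_table["new", "never"] - E["new", "never"])
      z <- direction * sqrt(pc$statistic)
    }
  }
  structure(
    list(
      name = name, group = group, per_occasion = per_occasion,
      pooled_table = pooled_table,
      chisq = if (undefined) NA_real_ else chisq,
      df = df,
      p_value = if (undefined) NA_real_ else pchisq(chisq, df, lower.tail = FALSE),
      z = z, undefined = undefined
    ),
    class = "gof_component"
  )
}

#' @export
print.gof_component <- function(x, ...) {
  cat(sprintf("<GOF component %s>%s\n", x$name,
    if (!is.na(x$group)) paste0(" group ", x$group) else ""))
  if (x$undefined) {
    cat("  no informative occasions: statistic undefined\n")
  } else {
    cat(sprintf(
      "  chi-square = %.3f on %d df, p = %.4g%s\n", x$chisq, x$df, x$p_value,
      if (!is.na(x$z)) sprintf(", directional z = %.3f", x$z) else ""
    ))
  }
  invisible(x)
}

#' @method tidy gof_component
#' @export
tidy.gof_component <- function(x, ...) {
  x$per_occasion
}

#' @method glance gof_component
#' @export
glance.gof_component <- function(x, ...) {
  tibble::tibble(
    name = x$name, group = x$group, chisq = x$chisq, df = x$df,
    p_value = x$p_value, z = x$z, undefined = x$undefined
  )
}

gof_3sr_one <- function(H) {
  K <- ncol(H)
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])
  rows <- vector("list", K)
  pooled <- matrix(0, 2, 2, dimnames = list(c("new", "old"), c("reseen", "never")))
  for (t in 2:(K - 1L)) {
    seen_t <- H[, t] == 1L
    if (!any(seen_t)) {
      rows[[t]] <- tibble::tibble(
        occasion = t, new_reseen = 0L, new_never = 0L,
        old_reseen = 0L, old_never = 0L,
        statistic = NA_real_, df = 0L, method = "uninformative"
      )
      next
    }
    is_new <- first == t
    reseen <- rowSums(H[, (t + 1L):K, drop = FALSE]) > 0
    tab <- matrix(
      c(
        sum(seen_t & is_new & reseen), sum(seen_t & is_new & !reseen),
        sum(seen_t & !is_new & reseen), sum(seen_t & !is_new & !reseen)
      ),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("new", "old"), c("reseen", "never"))
    )
    contrib <- table_contribution(tab)
    if (contrib$df > 0) pooled <- pooled + tab
    rows[[t]] <- tibble::tibble(
      occasion = t,
      new_reseen = tab["new", "reseen"], new_never = tab["new", "never"],
      old_reseen = tab["old", "reseen"], old_never = tab["old", "never"],
      statistic = contrib$statistic, df = contrib$df, method = contrib$method
    )
  }
  list(per_occasion = dplyr::bind_rows(rows), pooled = pooled)
}

#' Goodness-of-fit test 3.SR for transience
#'
#' For each interior occasion t, animals encountered at t are cross-classified
#' as newly versus previously encountered, and as re-encountered after t
#' versus never seen again. Under the CJS model the two rows are homogeneous;
#' an excess of newly encountered animals that are never seen again is the
#' signature of transients. Occasions whose expected cell counts fall below 2
#' contribute Fisher's exact test (converted to an equivalent 1-df
#' chi-square) instead of Pearson's statistic; the per-occasion method is
#' recorded in the output. A signed directional statistic `z` (the signed
#' square root of the pooled 2x2 Pearson chi-square, positive in the
#' transience direction) accompanies the omnibus chi-square.
#'
#' @param data An `encounter_df` with at least 3 occasions.
#' @param by_group Also run the test separately within each
#'   age-at-first-breeding group.
#' @return A `gof_component` (or, with `by_group = TRUE`, a list with the
#'   pooled component under `$pooled` and one component per group under
#'   `$by_group`).
#' @export
test_3sr <- function(data, by_group = FALSE) {
  H <- history_matrix(data)
  if (ncol(H) < 3L) abort("test 3.SR needs at least 3 occasions")
  res <- gof_3sr_one(H)
  pooled <- new_gof_component("3.SR", res$per_occasion, res$pooled)
  if (!by_group) {
    return(pooled)
  }
  by_g <- lapply(levels(data$group), function(g) {
    Hg <- H[data$group == g, , drop = FALSE]
    if (nrow(Hg) == 0L) {
      return(NULL)
    }
    r <- gof_3sr_one(Hg)
    new_gof_component("3.SR", r$per_occasion, r$pooled, group = g)
  })
  names(by_g) <- levels(data$group)
  list(pooled = pooled, by_group = by_g[!vapply(by_g, is.null, logical(1))])
}

#' Goodness-of-fit test 3.Sm (memory of previous encounters)
#'
#' Among previously encountered animals seen at occasion t, cross-classifies
#' the time since the previous encounter (lag classes 1, 2, 3+) against
#' whether the animal is re-encountered after t. Under the CJS model the lag
#' carries no information. Together with 3.SR this makes up Test 3 of
#' RELEASE.
#'
#' @param data An `encounter_df` with at least 4 occasions.
#' @return A `gof_component` (no directional statistic).
#' @export
test_3sm <- function(data) {
  H <- history_matrix(data)
  K <- ncol(H)
  if (K < 4L) abort("test 3.Sm needs at least 4 occasions")
  first <- apply(H, 1L, function(h) which(h == 1L)[1L])
  rows <- vector("list", K)
  for (t in 3:(K - 1L)) {
    sel <- which(H[, t] == 1L & first < t)
    if (length(sel) == 0L) {
      rows[[t]] <- tibble::tibble(
        occasion = t, statistic = NA_real_, df = 0L, method = "uninformative"
      )
      next
    }
    lag <- vapply(sel, function(i) {
      prev <- which(H[i, seq_len(t - 1L)] == 1L)
      t - max(prev)
    }, numeric(1))
    lag_class <- factor(pmin(lag, 3L), levels = 1:3,
      labels = c("lag1", "lag2", "lag3plus"))
    reseen <- factor(
      rowSums(H[sel, (t + 1L):K, drop = FALSE]) > 0,
      levels = c(TRUE, FALSE), labels = c("reseen", "never")
    )
    tab <- table(lag_class, reseen)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) {
      rows[[t]] <- tibble::tibble(
        occasion = t, statistic = NA_real_, df = 0L, method = "uninformative"
      )
      next
    }
    contrib <- table_contribution(as.matrix(tab))
    rows[[t]] <- tibble::tibble(
      occasion = t, statistic = contrib$statistic, df = contrib$df,
      method = contrib$method
    )
  }
  new_gof_component("3.Sm", dplyr::bind_rows(rows))
}

#' Overdispersion factor from goodness-of-fit components
#'
#' The variance inflation factor c-hat is the summed chi-square of the
#' supplied components divided by their summed degrees of freedom; the
#' fraction of the total lack of fit attributable to each component is also
#' returned (transients typically dominate when test 3.SR is strongly
#' significant).
#'
#' @param components A list of `gof_component` objects (or a single one).
#' @return A list with `c_hat`, `total_chisq`, `total_df` and
#'   `fraction_by_component` (named by component).
#' @export
estimate_chat <- function(components) {
  if (inherits(components, "gof_component")) components <- list(components)
  chis <- vapply(components, function(x) {
    if (isTRUE(x$undefined)) 0 else x$chisq
  }, numeric(1))
  dfs <- vapply(components, function(x) x$df, numeric(1))
  nm <- vapply(components, function(x) x$name, character(1))
  if (sum(dfs) == 0) abort("c-hat undefined: no degrees of freedom in the supplied components")
  names(chis) <- make.unique(nm)
  list(
    c_hat = sum(chis) / sum(dfs),
    total_chisq = sum(chis),
    total_df = sum(dfs),
    fraction_by_component = chis / sum(chis)
  )
}
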