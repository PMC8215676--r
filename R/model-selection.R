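#' Fit and rank candidate model families on the same data
#'
#' Each candidate family is fitted to `data` with [fit_growth()] and the
#' candidates are ranked by AIC, ascending (the study's criterion: high R^2
#' and low AIC).  Candidates whose fit failed outright or did not converge
#' are kept in the report but ranked last, so a selection can still be made
#' from the survivors.
#'
#' @param candidates Character vector of >= 2 family names (all 2D or all
#'   3D).
#' @param data Data frame with columns `t`, `dw` (and `I` for 3D families).
#' @param inits Optional named list of starting values per family.
#' @return An object of class `ltbr_selection`: list with `table` (one row
#'   per candidate: family, n, p, rss, r2, adj_r2, aic, f_value, p_f,
#'   converged, significant_f, explicit_asymptote, rank) sorted by rank, and
#'   `fits` (named list of `ltbr_fit` objects or `NULL` for failures).
#' @export
compare_models <- function(candidates, data, inits = NULL) {
  if (length(candidates) < 2) stop("need at least 2 candidate families")
  fits <- vector("list", length(candidates))
  names(fits) <- make.unique(candidates)
  for (i in seq_along(candidates)) {
    fam <- candidates[i]
    fits[[i]] <- tryCatch(
      fit_growth(fam, data, init = inits[[fam]]),
      error = function(e) NULL)
  }
  if (all(vapply(fits, is.null, logical(1))))
    stop("selection error: every candidate fit failed")
  row <- function(fam, fit) {
    if (is.null(fit))
      return(data.frame(family = fam, n = NA, p = n_params(fam),
                        rss = NA, r2 = NA, adj_r2 = NA, aic = NA,
                        f_value = NA, p_f = NA, converged = FALSE,
                        significant_f = FALSE,
                        explicit_asymptote = has_explicit_asymptote(fam)))
    data.frame(family = fam, n = fit$n, p = fit$p, rss = fit$gof$rss,
               r2 = fit$gof$r2, adj_r2 = fit$gof$adj_r2, aic = fit$gof$aic,
               f_value = fit$f_value, p_f = fit$p_f,
               converged = fit$converged,
               significant_f = isTRUE(fit$p_f < 0.05),
               explicit_asymptote = has_explicit_asymptote(fam))
  }
  tab <- do.call(rbind, Map(row, candidates, fits))
  # perfect fits have AIC = NaN (diverging to -Inf): rank them first;
  # failed/non-converged fits rank last; ties keep input order (stable sort)
  aic_key <- tab$aic
  aic_key[is.nan(aic_key) & !is.na(tab$rss)] <- -Inf
  aic_key[is.na(aic_key)] <- Inf
  aic_key[!tab$converged] <- Inf
  ord <- order(aic_key)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  tab <- tab[order(tab$rank), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "ltbr_selection")
}

#' @export
print.ltbr_selection <- function(x, ...) {
  cat("Model selection report (AIC ascending):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Choose the winning family from a selection report
#'
#' Selection rule:
#' * candidates must have converged and have a significant model F test
#'   (Prob > F < 0.05) — an insignificant control (the study's straight-line
#'   2D control) is never eligible, even if its AIC happens to be lowest;
#' * among eligible candidates within `delta_aic` (default 2.0, the
#'   conventional information-criterion equivalence band) of the best
#'   eligible AIC, the earliest family in `preference` wins — this encodes
#'   the study's interpretability tie-break, preferring families that
#'   explicitly expose the maximal achievable dry weight;
#' * otherwise the minimum-AIC eligible candidate wins.  A perfect fit
#'   (AIC diverging to `-Inf`) beats every finite AIC.
#'
#' @param report An `ltbr_selection` from [compare_models()].
#' @param preference Character vector of family names in decreasing
#'   preference; empty means pure AIC minimisation.
#' @param delta_aic Near-tie window on the AIC scale.
#' @return List with `family` (chosen name), `fit` (its `ltbr_fit`) and
#'   `justification` ("aic_minimum" or "preference_within_delta").
#' @export
choose_model <- function(report, preference = character(), delta_aic = 2.0) {
  stopifnot(inherits(report, "ltbr_selection"))
  tab <- report$table
  aic_key <- tab$aic
  aic_key[is.nan(aic_key) & !is.na(tab$rss)] <- -Inf
  eligible <- tab$converged & tab$significant_f & !is.na(tab$rss)
  if (!any(eligible))
    stop("selection error: no candidate is both converged and significant")
  et <- tab[eligible, , drop = FALSE]
  ek <- aic_key[eligible]
  best <- min(ek)
  near <- if (is.infinite(best)) is.infinite(ek) & ek < 0 else
    ek <= best + delta_aic
  pick <- et$family[near][1]
  justification <- "aic_minimum"
  if (length(preference)) {
    pref_hit <- preference[preference %in% et$family[near]]
    if (length(pref_hit) && pref_hit[1] != pick) {
      pick <- pref_hit[1]
      justification <- "preference_within_delta"
    } else if (length(pref_hit)) {
      pick <- pref_hit[1]
      justification <- if (sum(near) > 1) "preference_within_delta"
                       else "aic_minimum"
    }
  }
  list(family = pick, fit = report$fits[[match(pick, names(report$fits))]],
       justification = justification)
}

#' Write a selection report as a delimited table
#'
#' @param report An `ltbr_selection`.
#' @param path Output file path (tab-separated, with header).
#' @param chosen Optional family name to flag in a `chosen` column.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path, chosen = NULL) {
  tab <- report$table
  tab$chosen <- if (is.null(chosen)) FALSE else tab$family == chosen
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
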