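#' Cohort-level treatment summary table
#'
#' Groups per-trace summaries by treatment and reports, per treatment, the
#' thermoregulator / non-thermoregulator counts (over all traces) and the
#' mean and standard error of each of the eight response variables (seven
#' thermoregulation parameters plus db) over thermoregulators only, matching
#' the convention that only thermoregulating traces enter the parameter
#' analysis. SE is NA for a single-trace cell.
#'
#' @param summaries Either a list of `therm_summary` objects or the data
#'   frame from [summaries_to_df].
#' @param manifest Optional cohort manifest; when given, every summary
#'   treatment label must appear in `manifest$treatment`.
#' @return A data frame, one row per treatment (in order of first
#'   appearance), with columns `treatment`, `n_thermoregulators`,
#'   `n_non_thermoregulators`, and `<var>_mean` / `<var>_se` for each
#'   response.
#' @export
summarize_cohort <- function(summaries, manifest = NULL) {
  df <- if (is.data.frame(summaries)) summaries else summaries_to_df(summaries)
  if (!is.null(manifest)) {
    unknown <- setdiff(unique(df$treatment), unique(manifest$treatment))
    if (length(unknown) > 0L) {
      stop("unknown treatment label(s): ", paste(unknown, collapse = ", "))
    }
  }
  vars <- c("mean_tsk", "mean_upper", "mean_lower", "tpr", "t_max",
            "pct_time_thermoregulating", "n_shuttles", "db")
  out <- lapply(unique(df$treatment), function(tre) {
    g <- df[df$treatment == tre, , drop = FALSE]
    thermo <- g[g$is_thermoregulator, , drop = FALSE]
    row <- data.frame(
      treatment = tre,
      n_thermoregulators = nrow(thermo),
      n_non_thermoregulators = nrow(g) - nrow(thermo),
      stringsAsFactors = FALSE
    )
    for (v in vars) {
      x <- thermo[[v]]
      x <- x[!is.na(x)]
      row[[paste0(v, "_mean")]] <- if (length(x) > 0L) mean(x) else NA_real_
      row[[paste0(v, "_se")]] <-
        if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
    }
    row
  })
  do.call(rbind, out)
}

#' Seedable permutation comparison of a per-trace statistic across treatments
#'
#' Replaces a parametric mixed-model layer with a self-contained randomization
#' test. The overall statistic is the variance of the group means, with all
#' labels permuted jointly; each pairwise contrast uses the absolute
#' difference of the two group means, permuting labels only among the traces
#' of those two groups (so a strong third group cannot dilute a contrast).
#' P-values use the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_perm)` and pairwise p-values are
#' Holm-adjusted. With `scheme = "within_animal"` (the default whenever
#' `animal` shows repeated ids, respecting a repeated-measures design),
#' labels are permuted within each animal only.
#'
#' @param values Numeric per-trace statistic.
#' @param groups Treatment label per trace.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param animal Optional animal id per trace (enables the within-animal
#'   scheme).
#' @param scheme `"auto"` (default), `"free"`, or `"within_animal"`.
#' @return A list: `overall_p`, `pairwise` (data frame with `group1`,
#'   `group2`, `observed_diff`, `p_raw`, `p_holm`), `n_perm`, `scheme`.
#' @export
permutation_test <- function(values, groups, n_perm = 10000, seed = NULL,
                             animal = NULL,
                             scheme = c("auto", "free", "within_animal")) {
  scheme <- match.arg(scheme)
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  keep <- is.finite(values)
  values <- values[keep]; groups <- groups[keep]
  if (!is.null(animal)) animal <- as.character(animal)[keep]
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 values")
  if (scheme == "auto") {
    scheme <- if (!is.null(animal) && anyDuplicated(animal) > 0L) {
      "within_animal"
    } else {
      "free"
    }
  }
  if (scheme == "within_animal" && is.null(animal)) {
    stop("within_animal scheme needs animal ids")
  }
  if (!is.null(seed)) set.seed(seed)

  make_permuter <- function(g, ids) {
    if (scheme == "free") {
      function() sample(g)
    } else {
      by_animal <- split(seq_along(g), ids)
      function() {
        for (idx in by_animal) g[idx] <- g[idx[sample.int(length(idx))]]
        g
      }
    }
  }
  perm_p <- function(vals, g, ids, stat_fn) {
    obs <- stat_fn(g)
    permute <- make_permuter(g, ids)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (stat_fn(permute()) >= obs - 1e-12) hits <- hits + 1L
    }
    c(obs = obs, p = (1 + hits) / (1 + n_perm))
  }

  overall <- perm_p(values, groups, animal, function(g) {
    stats::var(vapply(lev, function(l) mean(values[g == l]), numeric(1)))
  })

  pair_idx <- utils::combn(seq_along(lev), 2L)
  pairs <- lapply(seq_len(ncol(pair_idx)), function(j) {
    a <- lev[pair_idx[1L, j]]; b <- lev[pair_idx[2L, j]]
    sub <- groups %in% c(a, b)
    v <- values[sub]; g <- groups[sub]
    ids <- if (!is.null(animal)) animal[sub] else NULL
    res <- perm_p(v, g, ids, function(gg) {
      abs(mean(v[gg == a]) - mean(v[gg == b]))
    })
    data.frame(group1 = a, group2 = b, observed_diff = res[["obs"]],
               p_raw = res[["p"]], stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, pairs)
  pairwise$p_holm <- stats::p.adjust(pairwise$p_raw, method = "holm")

  list(overall_p = overall[["p"]], pairwise = pairwise, n_perm = n_perm,
       scheme = scheme)
}
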