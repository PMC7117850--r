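#' Two-way repeated-measures ANOVA (group x time)
#'
#' Split-plot decomposition for a between-subject group factor and a
#' within-subject time factor with one observation per animal per timepoint:
#' the group effect is tested against the between-animal stratum, time and
#' the interaction against the within-animal stratum. Animals missing any
#' timepoint are excluded listwise (but can still enter the per-timepoint
#' Tukey comparisons). No sphericity correction is applied by default; a
#' Greenhouse-Geisser flag is accepted and adjusts the within-stratum
#' degrees of freedom.
#'
#' @param data tidy table with columns animal, group, week, value (one
#'   parameter; filter with \code{parameter} if the column is present).
#' @param parameter optional parameter name to select.
#' @param gg apply a Greenhouse-Geisser epsilon correction to the
#'   within-stratum tests.
#' @return data.frame with one row per effect (group, week, group:week):
#'   Df, F, p.
#' @export
rm_anova <- function(data, parameter = NULL, gg = FALSE) {
  if (!is.null(parameter)) data <- data[data$parameter == parameter, ]
  stopifnot(all(c("animal", "group", "week", "value") %in% names(data)))
  data$group <- factor(data$group)
  data$weekf <- factor(data$week)
  data$animal <- factor(data$animal)
  if (nlevels(data$group) < 2 || nlevels(data$weekf) < 2)
    stop("rm_anova needs at least 2 groups and 2 timepoints")

  # listwise completion
  counts <- table(data$animal)
  complete <- names(counts)[counts == nlevels(data$weekf)]
  data <- droplevels(data[data$animal %in% complete, ])

  # degenerate input (no variance at all): every effect is absent
  if (var(data$value) == 0 || !is.finite(var(data$value)))
    return(data.frame(effect = c("group", "week", "group:week"),
                      Df = NA_real_, F = 0, p = 1))

  fit <- aov(value ~ group * weekf + Error(animal), data = data)
  s <- summary(fit)
  between <- s[["Error: animal"]][[1]]
  within <- s[["Error: Within"]][[1]]

  eff <- function(tab, name) {
    i <- match(name, trimws(rownames(tab)))
    c(Df = tab[i, "Df"], F = tab[i, "F value"], p = tab[i, "Pr(>F)"],
      Df_err = tab[nrow(tab), "Df"])
  }
  g <- eff(between, "group")
  w <- eff(within, "weekf")
  gw <- eff(within, "group:weekf")

  if (gg) {
    # Greenhouse-Geisser epsilon from the within-animal covariance
    wide <- tapply(data$value, list(data$animal, data$weekf), mean)
    S <- stats::cov(wide, use = "complete.obs")
    k <- ncol(S)
    dbar <- mean(diag(S)); sbar <- mean(S)
    num <- (k * (dbar - sbar))^2
    den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * sbar^2)
    epsilon <- max(1 / (k - 1), min(1, num / den))
    w["p"] <- pf(w["F"], epsilon * w["Df"], epsilon * w["Df_err"], lower.tail = FALSE)
    gw["p"] <- pf(gw["F"], epsilon * gw["Df"], epsilon * gw["Df_err"], lower.tail = FALSE)
  }

  out <- data.frame(effect = c("group", "week", "group:week"),
                    Df = c(g["Df"], w["Df"], gw["Df"]),
                    F = c(g["F"], w["F"], gw["F"]),
                    p = c(g["p"], w["p"], gw["p"]))
  # degenerate all-equal data: aov returns NaN F; report F = 0, p = 1
  zero <- !is.finite(out$F)
  out$F[zero] <- 0; out$p[zero] <- 1
  rownames(out) <- NULL
  out
}

#' Tukey pairwise comparisons at one timepoint
#'
#' One-way Tukey-Kramer studentised-range comparisons of the groups at a
#' single timepoint, supporting unequal group sizes.
#'
#' @param data tidy table (see \code{\link{rm_anova}}).
#' @param week the timepoint to compare at.
#' @param parameter optional parameter name to select.
#' @return data.frame with columns pair, diff, p_adj.
#' @export
tukey_pairs <- function(data, week, parameter = NULL) {
  if (!is.null(parameter)) data <- data[data$parameter == parameter, ]
  d <- droplevels(data[data$week == week, ])
  if (nlevels(factor(d$group)) < 2) stop("tukey_pairs needs >= 2 groups")
  d$group <- factor(d$group)
  hsd <- TukeyHSD(aov(value ~ group, data = d))$group
  data.frame(pair = rownames(hsd), diff = hsd[, "diff"],
             p_adj = hsd[, "p adj"], row.names = NULL)
}

#' Group mean and SD per timepoint
#'
#' @param data tidy table; all parameters are summarised.
#' @return data.frame group, week, parameter, n, mean, sd (sd is NA with a
#'   single animal).
#' @export
summarize_groups <- function(data) {
  if (!"parameter" %in% names(data)) data$parameter <- "value"
  agg <- aggregate(value ~ group + week + parameter, data = data,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = if (length(v) > 1) sd(v) else NA_real_))
  out <- cbind(agg[c("group", "week", "parameter")], as.data.frame(agg$value))
  out[order(out$parameter, out$week, out$group), ]
}

#' Full group comparison of a longitudinal table
#'
#' Omnibus repeated-measures ANOVA per parameter plus Tukey pairwise
#' comparisons at every timepoint, with significance flags for each group
#' against the designated reference (sham) group at alpha.
#'
#' @param data tidy table (animal, group, week, parameter, value).
#' @param sham name of the reference group.
#' @param alpha significance level.
#' @return list per parameter: \code{omnibus} (from \code{\link{rm_anova}}),
#'   \code{pairwise} (stacked \code{\link{tukey_pairs}} with a week column),
#'   \code{vs_sham} (group x week significance flags).
#' @export
compare_groups <- function(data, sham = "sham", alpha = 0.05) {
  if (!"parameter" %in% names(data)) data$parameter <- "value"
  res <- list()
  for (p in unique(data$parameter)) {
    dp <- data[data$parameter == p, ]
    omni <- rm_anova(dp)
    pw <- do.call(rbind, lapply(unique(dp$week), function(w) {
      tp <- tukey_pairs(dp, w)
      tp$week <- w
      tp
    }))
    sham_rows <- grepl(paste0("(^", sham, "-)|(-", sham, "$)"), pw$pair)
    vs <- pw[sham_rows, ]
    vs$group <- sub(paste0("^", sham, "-"), "",
                    sub(paste0("-", sham, "$"), "", vs$pair))
    vs$significant <- vs$p_adj < alpha
    res[[p]] <- list(omnibus = omni, pairwise = pw,
                     vs_sham = vs[c("group", "week", "diff", "p_adj", "significant")])
  }
  res
}
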