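#' Design of a longitudinal group study
#'
#' Emulates the layout of a tibial-loading animal study: a control, a sham
#' and several loaded groups, followed over a set of ages, with one or more
#' outcome parameters measured per animal per timepoint. Values are drawn
#' from a compound-symmetric multivariate normal: each animal gets a random
#' intercept carrying a fraction \code{correlation} of the variance, and
#' group effects are added as multiples of the baseline SD at chosen
#' timepoints.
#'
#' @param groups data.frame with columns \code{name}, \code{n_animals}
#'   (each >= 2). Defaults mirror a typical design: control (6), sham (6)
#'   and three loaded groups (10 each).
#' @param timepoints ages in weeks at which animals are measured.
#' @param parameters data.frame with columns \code{parameter}, \code{mean},
#'   \code{sd} (baseline level and between-animal SD; sd > 0).
#' @param effects data.frame with columns \code{group}, \code{week},
#'   \code{parameter}, \code{effect_sd}: additive shifts in units of the
#'   parameter's SD. Empty by default (global null).
#' @param correlation within-animal correlation across timepoints, in [0, 1).
#' @param seed integer seed.
#' @export
study_design <- function(groups = data.frame(
                           name = c("control", "sham", "low", "medium", "high"),
                           n_animals = c(6, 6, 10, 10, 10)),
                         timepoints = c(11, 14, 22, 34, 52),
                         parameters = data.frame(parameter = "BV_TV",
                                                 mean = 0.25, sd = 0.03),
                         effects = NULL,
                         correlation = 0.6, seed = 1L) {
  stopifnot(is.data.frame(groups), all(c("name", "n_animals") %in% names(groups)),
            length(timepoints) >= 1,
            all(c("parameter", "mean", "sd") %in% names(parameters)))
  if (any(groups$n_animals < 2))
    stop("every group needs n_animals >= 2 (repeated-measures df requirement)")
  if (any(parameters$sd <= 0)) stop("baseline SDs must be positive")
  if (correlation < 0 || correlation >= 1)
    stop("within-animal correlation must lie in [0, 1)")
  if (is.null(effects))
    effects <- data.frame(group = character(), week = numeric(),
                          parameter = character(), effect_sd = numeric())
  structure(list(groups = groups, timepoints = sort(timepoints),
                 parameters = parameters, effects = effects,
                 correlation = correlation, seed = as.integer(seed)),
            class = "study_design")
}

#' Simulate a longitudinal measurement table from a study design
#'
#' @param design a \code{\link{study_design}}.
#' @return tidy data.frame with columns \code{animal}, \code{group},
#'   \code{week}, \code{parameter}, \code{value}; one row per
#'   animal x timepoint x parameter.
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  rho <- design$correlation
  tp <- design$timepoints
  nt <- length(tp)

  rows <- list()
  aid <- 0
  for (gi in seq_len(nrow(design$groups))) {
    gname <- design$groups$name[gi]
    for (a in seq_len(design$groups$n_animals[gi])) {
      aid <- aid + 1
      animal <- sprintf("%s_%02d", gname, a)
      for (pi in seq_len(nrow(design$parameters))) {
        p <- design$parameters[pi, ]
        # compound symmetry: shared intercept + independent residuals
        intercept <- rnorm(1, sd = sqrt(rho))
        resid <- rnorm(nt, sd = sqrt(1 - rho))
        vals <- p$mean + p$sd * (intercept + resid)
        ef <- design$effects
        ef <- ef[ef$group == gname & ef$parameter == p$parameter, , drop = FALSE]
        if (nrow(ef)) {
          j <- match(ef$week, tp)
          if (anyNA(j)) stop("effect at a week not in the design timepoints")
          vals[j] <- vals[j] + ef$effect_sd * p$sd
        }
        rows[[length(rows) + 1]] <- data.frame(
          animal = animal, group = gname, week = tp,
          parameter = p$parameter, value = vals)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- factor(out$group, levels = design$groups$name)
  out
}

#' Write / read a tidy study table as CSV
#'
#' Columns \code{animal}, \code{group}, \code{week}, \code{parameter},
#' \code{value}.
#'
#' @param data tidy data.frame as returned by \code{\link{generate_study}}.
#' @param path CSV path.
#' @param group_levels optional explicit group factor levels for reading.
#' @export
write_study <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path, group_levels = NULL) {
  df <- read.csv(path)
  df$group <- if (is.null(group_levels)) factor(df$group)
              else factor(df$group, levels = group_levels)
  df
}
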