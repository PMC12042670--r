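#' MyHC fiber type levels
#'
#' The five fiber classes used throughout: pure types 1, 2a, 2x and the
#' hybrid co-expression classes 1/2a and 2a/2x; fibers matching no rule are
#' `unclassified`.
#'
#' @export
fiber_type_levels <- c("1", "2a", "2x", "1/2a", "2a/2x", "unclassified")

#' Classify fibers from three-channel antibody intensities
#'
#' Operationalizes the antibody reactivities — BA-D5 binds the slow MyHC-1
#' isoform, SC-71 binds MyHC-2a and (weakly) MyHC-2x, 6H1 binds MyHC-2x —
#' as a threshold rule on normalized `[0, 1]` intensities. With
#' `B = (BAD5 >= tau_pos)`, `S = (SC71 >= tau_pos)`,
#' `Sstrong = (SC71 >= tau_strong)`, `H = (X6H1 >= tau_pos)`:
#'
#' * `B & !S & !H` -> type 1
#' * `B & S & !H` -> hybrid 1/2a
#' * `!B & S & !H` -> type 2a
#' * `!B & Sstrong & H` -> hybrid 2a/2x
#' * `!B & S & !Sstrong & H` -> type 2x (SC-71 cross-reacts weakly with 2x)
#' * anything else (all-negative, `B & H`, triple-positive) -> unclassified
#'
#' The two-level SC-71 threshold separates pure 2x fibers (weak
#' cross-reaction) from genuine 2a/2x hybrids (strong SC-71). Triple
#' positives are not a class here and are flagged unclassified with a
#' warning.
#'
#' @param bad5,sc71,x6h1 numeric vectors of normalized intensities in
#'   `[0, 1]`.
#' @param tau_pos positivity threshold (default 0.3).
#' @param tau_strong strong-SC71 threshold (default 0.6);
#'   `0 <= tau_pos < tau_strong <= 1`.
#' @return Factor of type calls with levels [fiber_type_levels].
#' @export
classify_fiber <- function(bad5, sc71, x6h1, tau_pos = 0.3, tau_strong = 0.6) {
  if (!(tau_pos >= 0 && tau_pos < tau_strong && tau_strong <= 1))
    stop("thresholds must satisfy 0 <= tau_pos < tau_strong <= 1")
  v <- c(bad5, sc71, x6h1)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("intensities must be finite and within [0, 1]")
  B <- bad5 >= tau_pos
  S <- sc71 >= tau_pos
  Ss <- sc71 >= tau_strong
  H <- x6h1 >= tau_pos
  out <- rep("unclassified", length(B))
  out[B & !S & !H] <- "1"
  out[B & S & !H] <- "1/2a"
  out[!B & S & !H] <- "2a"
  out[!B & Ss & H] <- "2a/2x"
  out[!B & S & !Ss & H] <- "2x"
  if (any(B & S & H))
    warning(sum(B & S & H), " triple-positive fiber(s) left unclassified")
  factor(out, levels = fiber_type_levels)
}

#' Summarize fiber types
#'
#' Counts, percentages (of classified fibers; unclassified reported
#' separately), and mean +/- SD of diameter and cross-sectional area per
#' type. SD is the sample SD (n - 1), reported as `NA` for n = 1.
#'
#' @param records data.frame with a factor/character column `type_call` and
#'   optional numeric columns `diameter` (um) and `csa` (um^2).
#' @return An object of class `type_summary`: data.frame with one row per
#'   type (`type, count, percent, diameter_mean, diameter_sd, csa_mean,
#'   csa_sd`), plus attributes `n_classified` and `n_unclassified`.
#' @export
summarize_types <- function(records) {
  type <- factor(as.character(records$type_call), levels = fiber_type_levels)
  classified <- type != "unclassified" & !is.na(type)
  if (!any(classified)) stop("no classified fibers to summarize")
  ctype <- droplevels(factor(type[classified],
                             levels = setdiff(fiber_type_levels, "unclassified")))
  ctype <- factor(as.character(ctype), levels = setdiff(fiber_type_levels, "unclassified"))
  counts <- table(ctype)
  stat <- function(colname) {
    if (is.null(records[[colname]]))
      return(list(mean = rep(NA_real_, length(counts)),
                  sd = rep(NA_real_, length(counts))))
    v <- records[[colname]][classified]
    m <- tapply(v, ctype, mean)
    s <- tapply(v, ctype, function(x) if (length(x) > 1) sd(x) else NA_real_)
    list(mean = as.numeric(m), sd = as.numeric(s))
  }
  dm <- stat("diameter"); cs <- stat("csa")
  out <- data.frame(type = names(counts), count = as.integer(counts),
                    percent = 100 * as.integer(counts) / sum(counts),
                    diameter_mean = dm$mean, diameter_sd = dm$sd,
                    csa_mean = cs$mean, csa_sd = cs$sd)
  attr(out, "n_classified") <- sum(classified)
  attr(out, "n_unclassified") <- sum(!classified)
  class(out) <- c("type_summary", "data.frame")
  out
}

#' @export
print.type_summary <- function(x, ...) {
  cat(sprintf("<type_summary> %d classified fibers (+%d unclassified)\n",
              attr(x, "n_classified"), attr(x, "n_unclassified")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Type fibers from an intensity table
#'
#' Convenience wrapper: reads (or accepts) a table with columns `fiber_id`,
#' `intensity_bad5`, `intensity_sc71`, `intensity_6h1` and optional
#' `diameter`/`csa`, classifies every fiber and summarizes.
#'
#' @param x data.frame or path to a CSV in the stain-table dialect.
#' @inheritParams classify_fiber
#' @return List with `records` (input plus `type_call`) and `summary` (a
#'   [summarize_types()] table).
#' @export
type_fibers <- function(x, tau_pos = 0.3, tau_strong = 0.6) {
  d <- if (is.character(x)) read.csv(x) else x
  d$type_call <- classify_fiber(d$intensity_bad5, d$intensity_sc71,
                                d$intensity_6h1, tau_pos, tau_strong)
  list(records = d, summary = summarize_types(d))
}
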