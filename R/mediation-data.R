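#' Construct an individual-level mediation dataset
#'
#' Container for case-control (or cohort) mediation data: a binary outcome
#' \code{y}, a binary exposure \code{a}, a mediator \code{m} (continuous or
#' binary) and optional baseline covariates \code{c}. All downstream fitting
#' and effect-estimation functions operate on this class.
#'
#' @param y binary outcome vector (0/1).
#' @param a binary exposure vector (0/1).
#' @param m mediator vector; must be 0/1 when \code{mediator_type = "binary"}.
#' @param c covariate matrix (n x k), data.frame, or NULL for no covariates.
#' @param mediator_type "continuous" or "binary".
#' @return an object of class \code{mediation_data} with elements
#'   \code{y}, \code{a}, \code{m}, \code{c} (always a numeric matrix, possibly
#'   zero-column), \code{mediator_type} and \code{n}.
#' @examples
#' d <- mediation_data(y = c(0, 1, 0, 1), a = c(0, 0, 1, 1),
#'                     m = c(0.2, 1.5, 0.7, 2.1),
#'                     c = cbind(c1 = c(1, 0, 1, 0)))
#' d$n
#' @export
mediation_data <- function(y, a, m, c = NULL, mediator_type = c("continuous", "binary")) {
  mediator_type <- match.arg(mediator_type)
  y <- as.numeric(y); a <- as.numeric(a); m <- as.numeric(m)
  n <- length(y)
  if (n < 1L) stop("at least one record is required")
  if (length(a) != n || length(m) != n)
    stop("y, a and m must have equal length")
  if (is.null(c)) {
    c <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    c <- as.matrix(c)
    storage.mode(c) <- "double"
    if (nrow(c) != n) stop("covariate matrix must have one row per record")
    if (is.null(colnames(c))) colnames(c) <- paste0("c", seq_len(ncol(c)))
  }
  if (anyNA(y) || anyNA(a) || anyNA(m) || anyNA(c)) {
    bad <- which(is.na(y) | is.na(a) | is.na(m) | rowSums(is.na(c)) > 0)
    stop("missing values in records: ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!all(y %in% c(0, 1))) stop("outcome y must be coded 0/1")
  if (!all(a %in% c(0, 1))) stop("exposure a must be coded 0/1")
  if (mediator_type == "binary" && !all(m %in% c(0, 1)))
    stop("binary mediator must be coded 0/1")
  structure(
    list(y = y, a = a, m = m, c = c, mediator_type = mediator_type, n = n),
    class = "mediation_data"
  )
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf("<mediation_data> n = %d (%d cases, %d controls), %s mediator, %d covariate(s)\n",
              x$n, sum(x$y == 1), sum(x$y == 0), x$mediator_type, ncol(x$c)))
  invisible(x)
}

#' Read a mediation dataset from a delimited text file
#'
#' Reads a CSV (or other delimited) file with a header row and maps named
#' columns onto the outcome, exposure, mediator and covariates. Rows with
#' missing values in any mapped column are rejected with a row-indexed error.
#'
#' @param file path to a delimited text file with a header.
#' @param outcome,exposure,mediator column names for Y, A and M.
#' @param covariates character vector of covariate column names (may be empty).
#' @param mediator_type "continuous" or "binary".
#' @param sep field separator, "," by default.
#' @return a \code{\link{mediation_data}} object.
#' @export
read_mediation_data <- function(file, outcome, exposure, mediator,
                                covariates = character(0),
                                mediator_type = c("continuous", "binary"),
                                sep = ",") {
  mediator_type <- match.arg(mediator_type)
  df <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  need <- c(outcome, exposure, mediator, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("columns not found in ", file, ": ", paste(missing_cols, collapse = ", "))
  sub <- df[need]
  if (anyNA(sub)) {
    bad <- which(rowSums(is.na(sub)) > 0)
    stop("missing values in rows: ", paste(utils::head(bad, 10L), collapse = ", "))
  }
  cmat <- if (length(covariates)) as.matrix(df[covariates]) else NULL
  mediation_data(y = df[[outcome]], a = df[[exposure]], m = df[[mediator]],
                 c = cmat, mediator_type = mediator_type)
}

#' Case-control analysis design specification
#'
#' Declares how the case-control sampling design is handled when fitting the
#' outcome and mediator models:
#' \describe{
#'   \item{naive}{ignore the design; unit weights everywhere.}
#'   \item{controls_only}{outcome model on the full sample; mediator model on
#'     controls only (valid as an approximation under a rare outcome).}
#'   \item{ipw}{inverse-probability weights \eqn{\pi/p} for cases and
#'     \eqn{(1-\pi)/(1-p)} for controls applied to both models; requires the
#'     population outcome prevalence \code{pi}.}
#'   \item{unified}{joint prospective likelihood for (M, Y); no prevalence
#'     needed.}
#' }
#'
#' @param strategy one of "naive", "controls_only", "ipw", "unified".
#' @param pi population outcome prevalence in (0, 1); required iff
#'   \code{strategy = "ipw"} and forbidden for "unified".
#' @param ci_methods subset of c("delta", "percentile_bootstrap").
#' @return an object of class \code{design_spec}.
#' @export
design_spec <- function(strategy = c("naive", "controls_only", "ipw", "unified"),
                        pi = NULL, ci_methods = "delta") {
  strategy <- match.arg(strategy)
  if (!all(ci_methods %in% c("delta", "percentile_bootstrap")))
    stop("ci_methods must be a subset of {delta, percentile_bootstrap}")
  if (strategy == "ipw") {
    if (is.null(pi)) stop("strategy 'ipw' requires the population prevalence pi")
    if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
      stop("pi must be a single probability strictly between 0 and 1")
  } else if (strategy == "unified" && !is.null(pi)) {
    stop("strategy 'unified' does not use a prevalence; leave pi = NULL")
  } else if (!is.null(pi) && (!is.numeric(pi) || pi <= 0 || pi >= 1)) {
    stop("pi must be a single probability strictly between 0 and 1")
  }
  structure(list(strategy = strategy, pi = pi, ci_methods = ci_methods),
            class = "design_spec")
}

#' Exposure contrast for natural effects
#'
#' Defines the exposure change a* -> a and the covariate values at which
#' conditional natural effects are evaluated.
#'
#' @param a treated exposure level (default 1).
#' @param a_star reference exposure level (default 0).
#' @param c conditioning covariate vector, or NULL to use sample-specific
#'   covariate means at estimation time.
#' @return an object of class \code{contrast_spec}.
#' @export
contrast_spec <- function(a = 1, a_star = 0, c = NULL) {
  if (identical(a, a_star)) stop("a and a_star must differ")
  structure(list(a = a, a_star = a_star, c = c), class = "contrast_spec")
}
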