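# Internal unit system is strict SI (mol/L and seconds). Micromolar and hours
# appear only at I/O boundaries; convert immediately on entry.

#' Unit conversions for concentrations and times
#'
#' Helpers converting the assay-sheet units (micromolar, hours) to the
#' internal SI units (molar, seconds) and back. All model-facing functions
#' in this package take molar and seconds.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @examples
#' uM_to_M(34.8)     # 3.48e-05
#' per_h_to_per_s(log(2) / 19)
#' @name units
NULL

#' @rdname units
#' @export
uM_to_M <- function(x) x * 1e-6

#' @rdname units
#' @export
M_to_uM <- function(x) x * 1e6

#' @rdname units
#' @export
h_to_s <- function(x) x * 3600

#' @rdname units
#' @export
s_to_h <- function(x) x / 3600

#' @rdname units
#' @export
per_h_to_per_s <- function(x) x / 3600

#' @rdname units
#' @export
per_s_to_per_h <- function(x) x * 3600

stop_domain <- function(...) {
  stop(structure(class = c("covkin_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_domain(name, " must be finite numeric")
  invisible(x)
}
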