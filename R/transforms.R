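#' Transform a pollinator density onto the modelling scale
#'
#' Wild bee densities are modelled on the log10 scale; hoverfly densities,
#' which include genuine zero counts, on the log10(x + 1) scale.  Residual
#' normality on these scales is what motivates fitting Gaussian mixed
#' models to count-derived densities.
#'
#' @param x Numeric vector of densities (individuals per 150 m2 transect),
#'   all `>= 0`.  The `"log10"` transform additionally requires `x > 0`.
#' @param transform `"log10"` (bees) or `"log10_plus1"` (hoverflies).
#' @return Numeric vector on the transformed scale.
#' @seealso [back_transform()] for the inverse.
#' @examples
#' transform_response(99, "log10_plus1")  # 2
#' back_transform(transform_response(7, "log10"), "log10")  # 7
#' @export
transform_response <- function(x, transform = c("log10", "log10_plus1")) {
  transform <- match.arg(transform)
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) {
    stop("densities must be non-negative", call. = FALSE)
  }
  if (transform == "log10") {
    if (any(x == 0, na.rm = TRUE)) {
      stop(
        "log10 transform is undefined at zero density; use the ",
        "'log10_plus1' (hoverfly) transform or a documented offset",
        call. = FALSE
      )
    }
    log10(x)
  } else {
    log10(x + 1)
  }
}

#' Back-transform a modelled value to the density scale
#'
#' Inverts [transform_response()]: `10^y` for `"log10"`, `10^y - 1`
#' (clamped at zero) for `"log10_plus1"`.
#'
#' @param y Numeric vector on the transformed scale.
#' @inheritParams transform_response
#' @return Densities (individuals per 150 m2 transect), always `>= 0`.
#' @export
back_transform <- function(y, transform = c("log10", "log10_plus1")) {
  transform <- match.arg(transform)
  if (transform == "log10") 10^y else pmax(10^y - 1, 0)
}

# canonical response transform per taxon
taxon_transform <- function(taxon) {
  switch(taxon,
    bee = "log10",
    hoverfly = "log10_plus1",
    stop("unknown taxon: ", taxon, call. = FALSE)
  )
}
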