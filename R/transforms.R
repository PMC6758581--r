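#' Trait transforms used before model fitting
#'
#' Nectar volume and amino-acid concentration are analysed on the log scale;
#' sugar concentration, sucrose proportion and amino-acid percentages on the
#' logit scale. Percentages are divided by 100 first, so logit offsets apply
#' on the proportion scale; an offset (e.g. 0.001) shifts values away from 0
#' before taking `log(p / (1 - p))`.
#'
#' @param values Named numeric vector (names are species).
#' @param kind `"log"` or `"logit"`.
#' @param offset Nonnegative offset added before a logit transform.
#' @param from_percent Divide by 100 before a logit transform.
#' @return Numeric vector with attributes `transform`, `offset`,
#'   `from_percent` recording how to invert.
#' @seealso [inverse_transform_trait()]
#' @export
#' @examples
#' transform_trait(c(a = 1), "log")                    # 0
#' transform_trait(c(a = 50), "logit", from_percent = TRUE)  # 0
transform_trait <- function(values, kind = c("log", "logit"), offset = 0,
                            from_percent = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(values), offset >= 0)
  x <- values
  if (kind == "log") {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      abort(paste0("log transform requires positive values; offending species: ",
                   paste(names(x)[bad], collapse = ", ")))
    }
    out <- log(x)
  } else {
    if (from_percent) x <- x / 100
    p <- x + offset
    bad <- !is.na(p) & (p <= 0 | p >= 1)
    if (any(bad)) {
      abort(paste0("logit transform requires values in (0, 1) after offset; ",
                   "offending species: ", paste(names(x)[bad], collapse = ", ")))
    }
    out <- log(p / (1 - p))
  }
  structure(out, transform = kind, offset = offset, from_percent = from_percent)
}

#' Back-transform a trait to its natural scale
#'
#' Inverts [transform_trait()]; results (optima, confidence limits) are
#' reported back-transformed.
#'
#' @param values Numeric vector on the transformed scale.
#' @param kind `"log"` or `"logit"`; defaults to the `transform` attribute.
#' @param offset,to_percent As recorded by [transform_trait()].
#' @return Numeric vector on the natural scale.
#' @export
inverse_transform_trait <- function(values, kind = NULL, offset = NULL,
                                    to_percent = NULL) {
  kind <- kind %||% attr(values, "transform")
  offset <- offset %||% attr(values, "offset") %||% 0
  to_percent <- to_percent %||% attr(values, "from_percent") %||% FALSE
  stopifnot(kind %in% c("log", "logit"))
  if (kind == "log") {
    out <- exp(as.numeric(values))
  } else {
    p <- 1 / (1 + exp(-as.numeric(values)))
    out <- p - offset
    if (to_percent) out <- out * 100
  }
  names(out) <- names(values)
  out
}
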