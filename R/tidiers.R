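#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.de_result <- function(x, ...) {
  attr(x, "stacked")
}

#' @export
glance.de_result <- function(x, ...) {
  tibble(
    n_rows = nrow(x), n_de = sum(x$is_de),
    n_pairs = length(unique(paste(attr(x, "stacked")$stage_a,
                                  attr(x, "stacked")$stage_b)))
  )
}

#' @export
tidy.family_age <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}
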