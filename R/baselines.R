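#' Local average filter
#'
#' Conventional local-means comparator: each pixel becomes the arithmetic
#' mean of its `k x k` neighborhood, with mirror padding at borders.
#'
#' @param img numeric matrix.
#' @param k odd kernel size >= 3 (typical comparator sizes: 5, 7, 15).
#' @return Filtered matrix.
#' @export
average_filter <- function(img, k = 5) {
  check_image(img)
  k <- as.integer(k)
  if (k < 3 || k %% 2 == 0) stop("kernel size must be odd and >= 3", call. = FALSE)
  .box_filter_cpp(img, (k - 1L) %/% 2L, FALSE)
}

#' Local median filter
#'
#' Each pixel becomes the median of its `k x k` neighborhood (mirror
#' padding). Output values are always drawn from the input value set.
#'
#' @inheritParams average_filter
#' @return Filtered matrix.
#' @export
median_filter <- function(img, k = 5) {
  check_image(img)
  k <- as.integer(k)
  if (k < 3 || k %% 2 == 0) stop("kernel size must be odd and >= 3", call. = FALSE)
  .box_filter_cpp(img, (k - 1L) %/% 2L, TRUE)
}
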