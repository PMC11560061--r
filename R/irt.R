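#' Construct a set of calibrated 2PL items
#'
#' An item is a (discrimination, difficulty) pair on the logit scale.  Scalars
#' are recycled, so `items(1, c(-1, 0, 1))` gives three items of equal
#' discrimination.
#'
#' @param a numeric vector of discriminations, all strictly positive and finite.
#' @param b numeric vector of difficulties (logit scale), all finite.
#' @return A data frame of class `irt_items` with columns `a` and `b`.
#' @examples
#' items(a = 1, b = c(-0.5, 0, 0.5))
#' @export
items <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("'a' and 'b' must be non-empty", call. = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n)
  b <- rep_len(as.numeric(b), n)
  validate_items(a, b)
  structure(data.frame(a = a, b = b), class = c("irt_items", "data.frame"))
}

validate_items <- function(a, b) {
  if (anyNA(a) || any(!is.finite(a)) || any(a <= 0))
    stop("item discriminations 'a' must be finite and > 0", call. = FALSE)
  if (anyNA(b) || any(!is.finite(b)))
    stop("item difficulties 'b' must be finite", call. = FALSE)
  invisible(TRUE)
}

as_items <- function(x) {
  if (inherits(x, "irt_items")) return(x)
  if (is.data.frame(x) && all(c("a", "b") %in% names(x))) return(items(x$a, x$b))
  stop("expected an 'irt_items' object or a data frame with columns a, b",
       call. = FALSE)
}

#' 2PL probability of a correct response
#'
#' Evaluates the two-parameter logistic response function
#' \deqn{p(\theta) = \frac{1}{1 + e^{-a(\theta - b)}}.}
#' The function is strictly increasing in ability and equals 1/2 at
#' \eqn{\theta = b}.
#'
#' @param item an [items()] object; a single item, or as many items as
#'   abilities.
#' @param theta numeric vector of abilities (logit scale), finite.
#' @return Numeric vector of response probabilities in (0, 1).
#' @examples
#' prob_correct(items(1, 0), theta = c(-1, 0, 1))
#' @export
prob_correct <- function(item, theta) {
  item <- as_items(item)
  check_theta(theta)
  if (nrow(item) > 1L && length(theta) > 1L && nrow(item) != length(theta))
    stop("when both have length > 1, 'item' and 'theta' must match", call. = FALSE)
  plogis(item$a * (theta - item$b))
}

check_theta <- function(theta) {
  if (length(theta) == 0L || anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite and non-empty", call. = FALSE)
  invisible(TRUE)
}

#' Fisher information of a 2PL item
#'
#' Item information is \eqn{I(\theta) = a^2 p(\theta)(1 - p(\theta))}; it peaks
#' at \eqn{\theta = b} with maximum \eqn{a^2/4}, so high-discrimination items
#' placed near the target ability carry the most information.
#'
#' @inheritParams prob_correct
#' @return Numeric vector of non-negative information values.
#' @examples
#' item_information(items(2, 0), theta = 0)  # a^2 / 4 = 1
#' @export
item_information <- function(item, theta) {
  item <- as_items(item)
  check_theta(theta)
  if (nrow(item) > 1L && length(theta) > 1L && nrow(item) != length(theta))
    stop("when both have length > 1, 'item' and 'theta' must match", call. = FALSE)
  # exp(-|x|)/(1+exp(-|x|))^2 is p(1-p) evaluated without overflow either way
  x <- item$a * (theta - item$b)
  t <- exp(-abs(x))
  item$a^2 * t / (1 + t)^2
}

#' Test information function
#'
#' The test information at an ability is the sum of the item informations, so
#' adding any item strictly increases it.  Its inverse is the asymptotic
#' variance of the maximum-likelihood ability estimate.
#'
#' @param its an [items()] object with at least one item.
#' @param theta numeric vector of abilities.
#' @return Numeric vector, one information value per ability.
#' @examples
#' test_information(items(1, c(-0.5, 0)), theta = -0.5)
#' @export
test_information <- function(its, theta) {
  its <- as_items(its)
  if (nrow(its) == 0L) stop("'its' must contain at least one item", call. = FALSE)
  check_theta(theta)
  x <- sweep(outer(theta, its$b, "-"), 2L, its$a, "*")
  t <- exp(-abs(x))
  rowSums(sweep(t / (1 + t)^2, 2L, its$a^2, "*"))
}
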