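# Colocalization category strings: ascending unique digits from 1-8, e.g.
# "358" marks an object positive for categories 3, 5 and 8. With 8 category
# slots there are 2^8 = 256 possible colocalization combinations.

#' Category string utilities
#'
#' `category_string()` normalizes digits into a valid category string
#' (sorted, unique). `category_add()` inserts a digit; `category_has()`
#' tests membership. `all_category_strings()` enumerates every nonempty
#' combination of the 8 category digits (255 strings; with the empty
#' combination the category space holds 2^8 = 256 combinations).
#'
#' @param digits integer vector of digits in 1..8.
#' @param category an existing category string.
#' @param digit single digit in 1..8.
#' @return character scalar (or vector for `all_category_strings()`).
#' @export
#' @examples
#' category_string(c(8, 3, 5)) # "358"
#' category_add("35", 8)       # "358"
category_string <- function(digits) {
  digits <- unique(as.integer(digits))
  if (length(digits) == 0) stop("category must be nonempty", call. = FALSE)
  if (any(digits < 1 | digits > 8)) {
    stop("category digits must lie in 1..8", call. = FALSE)
  }
  paste(sort(digits), collapse = "")
}

category_digits <- function(category) {
  as.integer(strsplit(as.character(category), "")[[1]])
}

#' @rdname category_string
#' @export
category_add <- function(category, digit) {
  category_string(c(category_digits(category), digit))
}

#' @rdname category_string
#' @export
category_has <- function(category, digit) {
  digit %in% category_digits(category)
}

#' @rdname category_string
#' @export
all_category_strings <- function() {
  combos <- unlist(lapply(1:8, function(k) {
    apply(utils::combn(1:8, k), 2, paste, collapse = "")
  }))
  combos
}
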