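#' Structural-context annotation alphabets
#'
#' An annotation alphabet maps each of the six structural categories a base
#' can occupy in a nested secondary structure (paired, hairpin loop,
#' external/unstructured, bulge, internal loop, multiloop) to a
#' single-character context letter. The default PLUM alphabet uses P for
#' paired, L for hairpin loop, U for external and folds the remaining
#' unpaired contexts (bulge, internal loop, multiloop) into the
#' miscellaneous letter M. A degenerate single-letter alphabet, in which
#' every category maps to the same letter, yields a structure-naive model
#' and is used for ablation.
#'
#' @param letters Ordered character vector of distinct single-character
#'   context labels.
#' @param category_map Named character vector mapping every one of the six
#'   structural categories to a letter in `letters`.
#' @return An `annotation_alphabet` object.
#' @examples
#' plum_alphabet()
#' single_letter_alphabet()
#' @export
annotation_alphabet <- function(letters, category_map) {
  letters <- as.character(letters)
  if (any(nchar(letters) != 1L) || anyDuplicated(letters)) {
    abort("`letters` must be distinct single characters.")
  }
  missing <- setdiff(CONTEXT_CATEGORIES, names(category_map))
  if (length(missing)) {
    abort(paste0("category_map misses categories: ",
                 paste(missing, collapse = ", ")))
  }
  category_map <- category_map[CONTEXT_CATEGORIES]
  if (!setequal(unique(unname(category_map)), letters)) {
    abort("`letters` must contain exactly the mapped letters.")
  }
  structure(list(letters = letters,
                 category_map = category_map),
            class = "annotation_alphabet")
}

#' @rdname annotation_alphabet
#' @export
plum_alphabet <- function() {
  annotation_alphabet(
    letters = c("P", "L", "U", "M"),
    category_map = c(paired = "P", hairpin_loop = "L", external = "U",
                     bulge = "M", internal_loop = "M", multiloop = "M")
  )
}

#' @rdname annotation_alphabet
#' @param letter Single character used for every category.
#' @export
single_letter_alphabet <- function(letter = "S") {
  annotation_alphabet(
    letters = letter,
    category_map = setNames(rep(letter, 6L), CONTEXT_CATEGORIES)
  )
}

#' @export
print.annotation_alphabet <- function(x, ...) {
  cat("<annotation_alphabet> letters:", paste(x$letters, collapse = ""), "\n")
  map <- split(names(x$category_map), unname(x$category_map))
  for (l in x$letters) {
    cat(" ", l, "<-", paste(map[[l]], collapse = ", "), "\n")
  }
  invisible(x)
}

# integer row index in `letters` for each C++ category code 0..5
alphabet_category_index <- function(alphabet) {
  match(unname(alphabet$category_map), alphabet$letters)
}

n_letters <- function(alphabet) length(alphabet$letters)

same_alphabet <- function(a, b) {
  identical(a$letters, b$letters) &&
    identical(unname(a$category_map), unname(b$category_map))
}
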