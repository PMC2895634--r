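#' Secondary structures and dot-bracket notation
#'
#' A secondary structure over a sequence of length n is stored as a partner
#' vector: `partner[i]` is the 0-based index paired with position i, or -1
#' for an unpaired base. Pairs are nested (non-crossing), so the structure
#' has an equivalent dot-bracket string over "(", ")" and ".".
#'
#' @param partner Integer vector of 0-based partners, -1 for unpaired.
#' @return A `secondary_structure` object with fields `n`, `partner` and
#'   `dotbracket`.
#' @examples
#' secondary_structure(partner_from_dotbracket("((...))"))
#' @export
secondary_structure <- function(partner) {
  partner <- as.integer(partner)
  n <- length(partner)
  paired <- which(partner >= 0L)
  if (length(paired)) {
    if (!all(partner[partner[paired] + 1L] == paired - 1L)) {
      abort("`partner` is not an involution.")
    }
  }
  db <- dotbracket_from_partner(partner)  # errors if crossing
  structure(list(n = n, partner = partner, dotbracket = db),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(x$dotbracket, "\n")
  invisible(x)
}

#' @rdname secondary_structure
#' @param dotbracket Dot-bracket string over "(", ")", ".".
#' @export
partner_from_dotbracket <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad)) {
    abort(paste0("illegal dot-bracket character: ", paste(bad, collapse = "")))
  }
  partner <- rep(-1L, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket string.")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket string.")
  partner
}

#' @rdname secondary_structure
#' @export
dotbracket_from_partner <- function(partner) {
  n <- length(partner)
  out <- rep(".", n)
  opened <- which(partner > seq_len(n) - 1L)
  if (length(opened)) {
    out[opened] <- "("
    out[partner[opened] + 1L] <- ")"
    # a crossing pair set re-parses to different partners
    reparsed <- tryCatch(partner_from_dotbracket(paste(out, collapse = "")),
                         error = function(e) NULL)
    if (is.null(reparsed) || !identical(reparsed, as.integer(partner))) {
      abort("pairs are crossing (not a nested structure).")
    }
  }
  paste(out, collapse = "")
}
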