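#' Read a tab-delimited affinity table
#'
#' Column 1 is the measured affinity, column 2 the RNA sequence; optional
#' columns 3 and 4 carry an id and a group tag ("stem_loop" or "weak").
#' T is silently mapped to U (one warning per file); any other non-ACGU
#' character, a malformed affinity or an empty sequence is an error naming
#' the offending line.
#'
#' @param path Input TSV (no header).
#' @return Tibble with columns `affinity`, `seq` and, when present, `id`
#'   and `group`.
#' @export
read_affinity_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty affinity table.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  warned_t <- FALSE
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 2L) {
      abort(paste0("line ", i, ": expected at least 2 tab-separated fields."))
    }
    aff <- suppressWarnings(as.numeric(f[1]))
    if (is.na(aff)) {
      abort(paste0("line ", i, ": malformed affinity '", f[1], "'."))
    }
    s <- toupper(f[2])
    if (!nzchar(s)) abort(paste0("line ", i, ": empty sequence."))
    if (grepl("T", s, fixed = TRUE)) {
      if (!warned_t) {
        warn("T bases mapped to U.")
        warned_t <<- TRUE
      }
      s <- gsub("T", "U", s, fixed = TRUE)
    }
    bad <- setdiff(strsplit(s, "")[[1]], RNA_BASES)
    if (length(bad)) {
      abort(paste0("line ", i, ": illegal character(s) ",
                   paste(bad, collapse = ", "), " in sequence."))
    }
    list(affinity = aff, seq = s,
         id = if (length(f) >= 3L) f[3] else sprintf("seq%05d", i),
         group = if (length(f) >= 4L) f[4] else NA_character_)
  })
  out <- tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    seq = vapply(rows, `[[`, character(1), "seq"),
    affinity = vapply(rows, `[[`, numeric(1), "affinity"),
    group = vapply(rows, `[[`, character(1), "group")
  )
  if (all(is.na(out$group))) out$group <- NULL
  out
}

#' Write / read score tables
#'
#' Deterministic TSV with a header row, fixed column order (id, then
#' label if present, then all numeric columns alphabetically) and floats
#' printed to 6 decimals, so a write-read round trip preserves values to
#' printed precision.
#'
#' @param rows Data frame of results.
#' @param path Output path.
#' @export
write_scores <- function(rows, path) {
  rows <- as_tibble(rows)
  lead <- intersect(c("id", "label", "fold", "scorer", "set", "group"),
                    names(rows))
  nums <- sort(setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                       lead))
  rest <- setdiff(names(rows), c(lead, nums))
  rows <- rows[, c(lead, sort(rest), nums), drop = FALSE]
  fmt <- vapply(seq_len(nrow(rows)), function(i) {
    paste(vapply(rows[i, ], function(v) {
      if (is.numeric(v)) sprintf("%.6f", v) else as.character(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(names(rows), collapse = "\t"), fmt), path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  as_tibble(df)
}

#' Read a FASTA file of RNA sequences
#'
#' Thin wrapper over a standard FASTA parse; T is mapped to U and
#' sequences are validated.
#'
#' @param path FASTA file.
#' @return Tibble with columns `id`, `seq`.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(ss))
    seqs <- unname(toupper(as.character(ss)))
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) abort("not a FASTA file.")
    ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
    grp <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                   collapse = "")
    seqs <- toupper(unname(seqs))
  }
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[i], "")[[1]], c(RNA_BASES, "N"))
    if (length(bad)) {
      abort(paste0("sequence ", ids[i], ": illegal character(s) ",
                   paste(bad, collapse = ", "), "."))
    }
  }
  tibble(id = ids, seq = seqs)
}

#' @rdname read_fasta
#' @param records Data frame with `id` and `seq` columns.
#' @export
write_fasta <- function(records, path) {
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", records$id)
  out[c(FALSE, TRUE)] <- records$seq
  writeLines(out, path)
  invisible(path)
}

# ---- annotation-profile file format ---------------------------------------

#' Write / read annotation profiles
#'
#' Bit-exact text format: a header line `#alphabet <letters>`, then per
#' sequence one identifier line `>id` followed by |A| lines
#' `<letter>\tp1\tp2...\tpn` with probabilities printed to 6 decimals.
#'
#' @param records Data frame with `id` and `profile` columns.
#' @param path Output path.
#' @export
write_profiles <- function(records, path) {
  records <- as_tibble(records)
  alphabet <- attr(records$profile[[1]], "alphabet")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#alphabet ", paste(alphabet$letters, collapse = "")),
             con)
  for (t in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[t]), con)
    prof <- records$profile[[t]]
    for (a in seq_len(nrow(prof))) {
      writeLines(paste(c(alphabet$letters[a],
                         sprintf("%.6f", prof[a, ])), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_profiles
#' @param alphabet Expected alphabet; when NULL it is reconstructed from
#'   the header with the default PLUM category map.
#' @export
read_profiles <- function(path, alphabet = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#alphabet ")) {
    abort("line 1: missing '#alphabet' header.")
  }
  letters <- strsplit(sub("^#alphabet ", "", lines[1]), "")[[1]]
  if (is.null(alphabet)) {
    alphabet <- if (identical(letters, c("P", "L", "U", "M"))) {
      plum_alphabet()
    } else if (length(letters) == 1L) {
      single_letter_alphabet(letters)
    } else {
      abort("line 1: unknown alphabet; pass `alphabet` explicitly.")
    }
  }
  na <- length(letters)
  i <- 2L
  ids <- character(0)
  profiles <- list()
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) {
      abort(paste0("line ", i, ": expected '>id' record header."))
    }
    id <- sub("^>", "", lines[i])
    block <- lines[i + seq_len(na)]
    rows <- lapply(seq_len(na), function(a) {
      f <- strsplit(block[a], "\t", fixed = TRUE)[[1]]
      if (f[1] != letters[a]) {
        abort(paste0("line ", i + a, ": expected letter ", letters[a], "."))
      }
      as.numeric(f[-1])
    })
    prof <- do.call(rbind, rows)
    rownames(prof) <- letters
    bad <- which(abs(colSums(prof) - 1) > 1e-6)
    if (length(bad)) {
      abort(paste0("record ", id, ": profile column ", bad[1],
                   " does not sum to 1."))
    }
    attr(prof, "alphabet") <- alphabet
    ids <- c(ids, id)
    profiles <- c(profiles, list(prof))
    i <- i + na + 1L
  }
  tibble(id = ids, profile = profiles)
}

#' Read / write dot-bracket sample files
#'
#' One structure per line; a blank line separates consecutive sequence
#' records.
#'
#' @param path File of dot-bracket strings.
#' @return List of character vectors, one per sequence record.
#' @export
read_dotbracket_samples <- function(path) {
  lines <- readLines(path)
  grp <- cumsum(!nzchar(lines))
  keep <- nzchar(lines)
  unname(split(lines[keep], grp[keep]))
}

# ---- motif-model file format ----------------------------------------------

#' Write / read a motif model file
#'
#' Plain-text, bit-exact format: `width <w>`; `alphabet <letters>`;
#' `convention <sum|mean>`; four `theta <base> v1..vw` lines; one
#' `gamma <letter>=<v> ...` line; `b_seq`, `b_str`, `slope`, `intercept`
#' lines. Values are printed to 10 significant digits.
#'
#' @param model A [motif_model()].
#' @param map An [affinity_map()].
#' @param path Output path.
#' @export
write_model <- function(model, map, path) {
  g10 <- function(x) sprintf("%.10g", x)
  lines <- c(
    paste("width", model$width),
    paste("alphabet", paste(model$alphabet$letters, collapse = "")),
    paste("convention", model$convention),
    vapply(seq_len(4L), function(b) {
      paste(c("theta", RNA_BASES[b], g10(model$theta[b, ])), collapse = " ")
    }, character(1)),
    paste("gamma", paste(sprintf("%s=%s", names(model$gamma),
                                 g10(model$gamma)), collapse = " ")),
    paste("b_seq", g10(model$b_seq)),
    paste("b_str", g10(model$b_str)),
    paste("slope", g10(map$slope)),
    paste("intercept", g10(map$intercept))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " +")
  key <- vapply(kv, `[`, character(1), 1L)
  get1 <- function(k) kv[[match(k, key)]][2]
  width <- as.integer(get1("width"))
  letters <- strsplit(get1("alphabet"), "")[[1]]
  alphabet <- if (identical(letters, c("P", "L", "U", "M"))) plum_alphabet()
              else if (length(letters) == 1L) single_letter_alphabet(letters)
              else abort("unknown alphabet in model file.")
  convention <- get1("convention")
  theta <- matrix(0, 4L, width, dimnames = list(RNA_BASES, NULL))
  for (row in which(key == "theta")) {
    b <- kv[[row]][2]
    theta[b, ] <- as.numeric(kv[[row]][-(1:2)])
  }
  gline <- kv[[match("gamma", key)]][-1]
  gparts <- strsplit(gline, "=", fixed = TRUE)
  gamma <- setNames(vapply(gparts, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(gparts, `[`, character(1), 1L))
  model <- motif_model(theta, gamma[letters],
                       b_seq = as.numeric(get1("b_seq")),
                       b_str = as.numeric(get1("b_str")),
                       alphabet = alphabet,
                       convention = convention)
  map <- affinity_map(as.numeric(get1("slope")),
                      as.numeric(get1("intercept")))
  list(model = model, map = map)
}
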