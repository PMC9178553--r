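# MSP (NIST-dialect) spectral-library text I/O.
#
# Record grammar:
#   Name: SEQUENCE/charge
#   Comment: CE=<eV> Source=<tag>        (optional line, optional tokens)
#   Num peaks: <n>
#   <mz>\t<intensity>\t<annotation>      (n lines; annotation e.g. y3, y5^2, b2)
# Records are separated by one or more blank lines.

ANNOT_RE <- "^([A-Za-z]+)([0-9]+)(\\^([0-9]+))?$"

parse_annotation <- function(ann) {
  m <- regmatches(ann, regexec(ANNOT_RE, ann))[[1]]
  if (length(m) == 0L) {
    # unparseable: keep the raw label as the series so later cleaning can drop it
    return(list(series = ann, ordinal = NA_integer_, fragment_charge = NA_integer_))
  }
  z <- if (m[5] == "") 1L else as.integer(m[5])
  list(series = m[2], ordinal = as.integer(m[3]), fragment_charge = z)
}

format_annotation <- function(series, ordinal, fragment_charge) {
  ifelse(is.na(ordinal), series,
         paste0(series, ordinal,
                ifelse(!is.na(fragment_charge) & fragment_charge > 1L,
                       paste0("^", fragment_charge), "")))
}

#' Read a NIST-style MSP spectral library
#'
#' Parses an MSP text stream into a [speclib()]. Peak annotations of the form
#' `y3`, `y5^2`, `b2` are decomposed into (series, ordinal, fragment charge);
#' annotations that do not match this grammar are retained with `series` set
#' to the raw label so that [drop_b_ions()] can remove them. Record order is
#' preserved.
#'
#' @param path Path to an MSP file, or a character vector of lines (useful
#'   for tests).
#' @param ce_keys Comment-line keys accepted for the collision energy, tried
#'   in order.
#' @param source Provenance tag recorded when the file itself carries none.
#' @return A [speclib()].
#' @export
read_msp <- function(path, ce_keys = c("CE", "NCE", "Collision_energy"),
                     source = NA_character_) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(speclib())

  name_idx <- which(startsWith(lines, "Name:"))
  if (!length(name_idx) && length(nonblank)) {
    stop("no 'Name:' line found; first content at line ", nonblank[1], call. = FALSE)
  }
  bounds <- c(name_idx, length(lines) + 1L)

  records <- vector("list", length(name_idx))
  for (r in seq_along(name_idx)) {
    i0 <- name_idx[r]
    block <- lines[i0:(bounds[r + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]

    name_val <- trimws(sub("^Name:", "", block[1]))
    nm <- regmatches(name_val, regexec("^([][A-Za-z()+.0-9-]+)/([0-9]+)$", name_val))[[1]]
    if (length(nm) == 0L) {
      stop(sprintf("malformed 'Name:' line at line %d: '%s'", i0, block[1]),
           call. = FALSE)
    }
    seq_str <- nm[2]
    charge <- as.integer(nm[3])

    ce <- NA_real_
    src <- source
    comment_i <- which(startsWith(block, "Comment:"))
    if (length(comment_i)) {
      tokens <- strsplit(trimws(sub("^Comment:", "", block[comment_i[1]])), "\\s+")[[1]]
      for (key in ce_keys) {
        hit <- grep(paste0("^", key, "="), tokens, value = TRUE)
        if (length(hit)) { ce <- as.numeric(sub(".*=", "", hit[1])); break }
      }
      src_hit <- grep("^Source=", tokens, value = TRUE)
      if (length(src_hit)) src <- sub("^Source=", "", src_hit[1])
    }

    np_i <- which(startsWith(block, "Num peaks:"))
    declared <- if (length(np_i)) as.integer(trimws(sub("^Num peaks:", "", block[np_i[1]]))) else NA_integer_
    peak_lines <- if (length(np_i) && np_i[1] < length(block)) {
      block[(np_i[1] + 1L):length(block)]
    } else character()
    peak_lines <- peak_lines[!grepl("^[A-Za-z]+ ?[A-Za-z]*:", peak_lines)]
    if (!is.na(declared) && declared != length(peak_lines)) {
      warning(sprintf("record '%s': 'Num peaks: %d' but %d peak line(s); keeping actual",
                      name_val, declared, length(peak_lines)), call. = FALSE)
    }

    if (length(peak_lines)) {
      fields <- strsplit(peak_lines, "\t", fixed = TRUE)
      ann <- lapply(fields, function(f) parse_annotation(if (length(f) >= 3) f[3] else ""))
      pk <- peak_tbl(
        series = vapply(ann, `[[`, character(1), "series"),
        ordinal = vapply(ann, `[[`, integer(1), "ordinal"),
        fragment_charge = vapply(ann, `[[`, integer(1), "fragment_charge"),
        mz = vapply(fields, function(f) as.numeric(f[1]), numeric(1)),
        intensity = vapply(fields, function(f) as.numeric(f[2]), numeric(1))
      )
    } else {
      pk <- peak_tbl()
    }
    records[[r]] <- list(sequence = seq_str, precursor_charge = charge,
                         collision_energy = ce, source = src, peaks = pk)
  }

  speclib(
    sequence = vapply(records, `[[`, character(1), "sequence"),
    precursor_charge = vapply(records, `[[`, integer(1), "precursor_charge"),
    collision_energy = vapply(records, `[[`, numeric(1), "collision_energy"),
    peaks = lapply(records, `[[`, "peaks"),
    source = vapply(records, `[[`, character(1), "source")
  )
}

#' Write a spectral library to MSP text
#'
#' Emits the same MSP dialect that [read_msp()] accepts; the round trip
#' `read_msp(write_msp(lib))` reproduces the library.
#'
#' @param lib A [speclib()].
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_msp <- function(lib, path = NULL) {
  out <- character(0)
  if (nrow(lib)) {
    blocks <- lapply(seq_len(nrow(lib)), function(i) {
      pk <- lib$peaks[[i]]
      comment <- c(
        if (!is.na(lib$collision_energy[i])) sprintf("CE=%.10g", lib$collision_energy[i]),
        if (!is.na(lib$source[i])) paste0("Source=", lib$source[i])
      )
      c(
        sprintf("Name: %s/%d", lib$sequence[i], lib$precursor_charge[i]),
        if (length(comment)) paste("Comment:", paste(comment, collapse = " ")),
        sprintf("Num peaks: %d", nrow(pk)),
        if (nrow(pk)) sprintf("%.12g\t%.12g\t%s", pk$mz, pk$intensity,
                              format_annotation(pk$series, pk$ordinal, pk$fragment_charge)),
        ""
      )
    })
    out <- unlist(blocks)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a plain peptide list
#'
#' One peptide per line in the form `SEQUENCE[/charge[/CE]]`. Missing charge
#' and collision energy are filled in with the supplied defaults, matching the
#' prediction interface where only the sequence is required.
#'
#' @param path File path or character vector of lines.
#' @param default_charge Charge used when a line carries none.
#' @param default_ce Collision energy (eV) used when a line carries none.
#' @return A tibble with columns `sequence`, `precursor_charge`,
#'   `collision_energy`.
#' @export
read_peptide_list <- function(path, default_charge = 2L, default_ce = 30) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "/", fixed = TRUE)
  tibble::tibble(
    sequence = vapply(parts, `[[`, character(1), 1L),
    precursor_charge = vapply(parts, function(p)
      if (length(p) >= 2L) as.integer(p[2]) else as.integer(default_charge), integer(1)),
    collision_energy = vapply(parts, function(p)
      if (length(p) >= 3L) as.numeric(p[3]) else as.numeric(default_ce), numeric(1))
  )
}
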