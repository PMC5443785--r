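# Canonical motif algebra for SSR repeat units (period 2-6).
#
# Two repeat units describe the same SSR class when one is a cyclic
# rotation of the other or of its reverse complement: a repeat tract read
# from any phase, on either strand, is the same locus. The class
# representative ("canonical motif") is the lexicographically smallest
# string in that orbit, which matches the convention of writing classes
# as AC/GT, AAAT/ATTT with the smaller member first.

.DNA_BASES <- c("A", "C", "G", "T")

.check_dna <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || is.na(unit))
    stop("repeat unit must be a single character string", call. = FALSE)
  chars <- strsplit(unit, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L || !all(chars %in% .DNA_BASES))
    stop("invalid alphabet: repeat unit must be over {A,C,G,T}, got '",
         unit, "'", call. = FALSE)
  chars
}

.revcomp <- function(chars) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[chars]))
}

.rotations <- function(chars) {
  n <- length(chars)
  vapply(seq_len(n), function(i) {
    paste(chars[c(seq.int(i, n), if (i > 1L) seq_len(i - 1L))],
          collapse = "")
  }, character(1L))
}

#' Test whether a repeat unit is primitive
#'
#' A unit is primitive when it is not a whole-number repetition of a
#' shorter unit (`"ACAC"` is `"AC"` twice, hence not primitive; a
#' homopolymer such as `"AAAA"` is not primitive either). Only primitive
#' units define an unambiguous repeat period.
#'
#' @param unit A single DNA string over `{A,C,G,T}`.
#' @return `TRUE` iff no proper divisor `d` of `nchar(unit)` exists such
#'   that `unit` equals its first `d` characters repeated.
#' @examples
#' is_primitive("ACG")   # TRUE
#' is_primitive("ACAC")  # FALSE
#' @export
is_primitive <- function(unit) {
  chars <- .check_dna(unit)
  n <- length(chars)
  if (n == 1L) return(TRUE)
  for (d in seq_len(n - 1L)) {
    if (n %% d != 0L) next
    if (all(chars == rep_len(chars[seq_len(d)], n))) return(FALSE)
  }
  TRUE
}

#' Canonical motif class of a repeat unit
#'
#' Maps a repeat unit to its class representative: the lexicographically
#' smallest string among all cyclic rotations of the unit and all cyclic
#' rotations of its reverse complement. Two units map to the same
#' canonical motif exactly when they describe the same repeat class read
#' in a different phase or from the other strand.
#'
#' @param unit A single DNA string of length 2-6 over `{A,C,G,T}`. Must
#'   be primitive (not a repetition of a shorter unit).
#' @return A single string: the canonical motif. Its `nchar()` is the
#'   period of the class.
#' @examples
#' canonical_motif("GT")    # "AC"
#' canonical_motif("TTTA")  # "AAAT"
#' @export
canonical_motif <- function(unit) {
  chars <- .check_dna(unit)
  n <- length(chars)
  if (n < 2L || n > 6L)
    stop("invalid period: repeat unit length must be in [2,6], got ",
         n, call. = FALSE)
  if (!is_primitive(unit))
    stop("non-primitive repeat unit '", unit,
         "': it repeats a shorter unit", call. = FALSE)
  orbit <- c(.rotations(chars), .rotations(.revcomp(chars)))
  # C-locale comparison so A < C < G < T regardless of session locale
  orbit[order(orbit, method = "radix")][1L]
}

#' Enumerate all canonical motif classes of one period
#'
#' Brute-force enumeration over all `4^period` units of the given length:
#' non-primitive units are dropped and the rest grouped into orbits under
#' rotation and reverse complementation. For periods 2-6 this yields
#' 4, 10, 33, 102 and 350 classes respectively.
#'
#' @param period Integer in `[2,6]`.
#' @return Character vector of canonical motifs, sorted lexicographically.
#' @examples
#' enumerate_motif_classes(2)  # "AC" "AG" "AT" "CG"
#' @export
enumerate_motif_classes <- function(period) {
  if (length(period) != 1L || is.na(period) || period != as.integer(period) ||
      period < 2L || period > 6L)
    stop("period must be a single integer in [2,6]", call. = FALSE)
  period <- as.integer(period)
  units <- do.call(paste0, expand.grid(rep(list(.DNA_BASES), period),
                                       stringsAsFactors = FALSE))
  units <- units[vapply(units, is_primitive, logical(1L))]
  canon <- vapply(units, canonical_motif, character(1L), USE.NAMES = FALSE)
  sort(unique(canon), method = "radix")
}
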