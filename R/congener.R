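# PBDE congener specifications: parsing, canonicalization, naming.
#
# A congener is a bromine substitution pattern on the diphenyl ether
# skeleton.  Positions 2..6 on each ring can carry Br; position 1 (ipso,
# bearing the ether bridge) never can.  The molecule has two symmetries:
# the two rings can be swapped, and each ring can be mirrored about the
# ipso axis (2 <-> 6, 3 <-> 5, 4 fixed).  All congener specs are stored in
# a canonical form modulo these symmetries.

#' Classed error helper
#' @noRd
qspr_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "mdevqspr_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' Mirror-normalize one ring's locant set
#'
#' Replaces the set by whichever of {set, 8 - set} has the
#' lexicographically smaller sorted tuple (standard lowest-locant rule).
#' @noRd
mirror_normalize <- function(positions) {
  a <- sort(as.integer(positions))
  b <- sort(8L - a)
  if (locant_lt(b, a)) b else a
}

#' Lexicographic order on sorted locant tuples
#'
#' Compares element-wise; when one tuple is a strict prefix of the other,
#' the *longer* tuple is the smaller (missing positions compare as
#' +infinity).  This makes the substituted ring sort before an
#' unsubstituted one, so "3-monoBDE" keeps its bromine on the unprimed
#' ring.
#' @noRd
locant_lt <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0L) {
    for (i in seq_len(k)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
  }
  length(a) > length(b)
}

homolog_prefixes <- c(
  "mono", "di", "tri", "tetra", "penta",
  "hexa", "hepta", "octa", "nona", "deca"
)

#' Canonical display name for a substitution pattern
#'
#' Locants are merged across rings in increasing order, unprimed before
#' primed at equal value, and suffixed with the homolog prefix, e.g.
#' "2,2′,4,4′-tetraBDE".
#' @noRd
congener_name <- function(ring_a, ring_b) {
  n <- length(ring_a) + length(ring_b)
  if (n == 0L) {
    return("diphenyl ether")
  }
  loc <- rbind(
    if (length(ring_a)) cbind(ring_a, 0L),
    if (length(ring_b)) cbind(ring_b, 1L)
  )
  loc <- loc[order(loc[, 1L], loc[, 2L]), , drop = FALSE]
  lab <- paste0(loc[, 1L], ifelse(loc[, 2L] == 1L, "′", ""))
  paste0(paste(lab, collapse = ","), "-", homolog_prefixes[n], "BDE")
}

check_positions <- function(positions, ring) {
  p <- suppressWarnings(as.integer(positions))
  if (length(p) && anyNA(p)) {
    qspr_error(sprintf("non-numeric locant on ring %s", ring), "parse_error")
  }
  bad <- p[p < 2L | p > 6L]
  if (length(bad)) {
    qspr_error(
      sprintf(
        "invalid ring position%s %s on ring %s: Br can occupy positions 2-6 only (position 1 is the ipso carbon)",
        if (length(bad) > 1L) "s" else "", paste(bad, collapse = ", "), ring
      ),
      "invalid_position_error"
    )
  }
  if (anyDuplicated(p)) {
    qspr_error(
      sprintf(
        "duplicate substitution at position %s on ring %s",
        paste(unique(p[duplicated(p)]), collapse = ", "), ring
      ),
      "duplicate_substitution_error"
    )
  }
  sort(p)
}

#' Construct a PBDE congener specification
#'
#' A congener is identified by the sets of brominated positions on the two
#' phenyl rings of the diphenyl ether skeleton.  The returned object is
#' canonical: each ring's locant set is mirror-normalized (2 <-> 6,
#' 3 <-> 5) to its lowest-locant form and the ring with the
#' lexicographically smaller locant tuple becomes ring A, so any two
#' symmetry-equivalent inputs yield identical objects.
#'
#' @param ring_a,ring_b Integer vectors of brominated positions, subsets
#'   of \code{2:6}.  Position 1 carries the ether bridge and cannot be
#'   substituted.
#' @return An object of class \code{congener_spec}: a list with elements
#'   \code{ring_a}, \code{ring_b} (sorted integer locants) and \code{name}
#'   (canonical text form, e.g. \code{"2,2′,4,4′-tetraBDE"}).
#' @examples
#' congener_spec(c(2, 4), c(2, 4))
#' congener_spec(c(6), integer())  # mirror-normalized to position 2
#' @seealso [parse_congener()], [compute_mdev()]
#' @export
congener_spec <- function(ring_a = integer(), ring_b = integer()) {
  a <- mirror_normalize(check_positions(ring_a, "A"))
  b <- mirror_normalize(check_positions(ring_b, "B"))
  if (locant_lt(b, a)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  structure(
    list(ring_a = a, ring_b = b, name = congener_name(a, b)),
    class = "congener_spec"
  )
}

#' @export
format.congener_spec <- function(x, ...) x$name

#' @export
print.congener_spec <- function(x, ...) {
  cat("<congener_spec> ", x$name, "\n", sep = "")
  invisible(x)
}

#' @export
as.character.congener_spec <- function(x, ...) x$name

#' Number of bromine substituents of a congener
#'
#' @param spec A \code{congener_spec}.
#' @return Integer count of bromines (0 to 10).
#' @export
n_bromines <- function(spec) {
  stopifnot(inherits(spec, "congener_spec"))
  length(spec$ring_a) + length(spec$ring_b)
}

# Characters accepted as the "prime" marking second-ring locants.
.prime_chars <- c("′", "ʹ", "´", "’", "`")

#' Parse a PBDE congener locant string
#'
#' Accepts the comma-separated locant notation used for BDE congeners,
#' e.g. \code{"2,2',4,4'"}: primed locants sit on the second ring.  Both
#' the ASCII apostrophe and the Unicode prime (\code{′}) are
#' accepted, as is surrounding whitespace and a trailing homolog suffix
#' such as \code{"-tetrabromo"}.
#'
#' @param text A single congener string.
#' @return A canonical [congener_spec()].
#' @examples
#' parse_congener("2,2',4,4'")
#' parse_congener("3 -monobromo")
#' identical(parse_congener("2,6"), parse_congener("2',6'"))
#' @export
parse_congener <- function(text) {
  if (length(text) != 1L || is.na(text) || !is.character(text)) {
    qspr_error("expected a single congener string", "parse_error")
  }
  x <- text
  for (ch in .prime_chars) x <- gsub(ch, "'", x, fixed = TRUE)
  x <- gsub("[[:space:]]", "", x)
  # drop a trailing homolog-name suffix ("-tetrabromo", "-hexaBDE", ...)
  x <- sub("-[^0-9,'].*$", "", x)
  if (!nzchar(x)) {
    qspr_error(
      "empty congener string (the unsubstituted spec must be built with congener_spec())",
      "empty_spec_error"
    )
  }
  tokens <- strsplit(x, ",", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens))) {
    qspr_error(sprintf("malformed congener string: '%s'", text), "parse_error")
  }
  m <- regmatches(tokens, regexec("^([0-9]+)('?)$", tokens))
  ok <- vapply(m, length, 1L) == 3L
  if (!all(ok)) {
    qspr_error(
      sprintf("malformed locant '%s' in '%s'", tokens[!ok][1L], text),
      "parse_error"
    )
  }
  vals <- vapply(m, function(g) as.integer(g[2L]), 1L)
  primed <- vapply(m, function(g) g[3L] == "'", TRUE)
  congener_spec(ring_a = vals[!primed], ring_b = vals[primed])
}

#' Enumerate all distinct canonical PBDE congeners
#'
#' Walks every pair of locant subsets of \code{{2..6}} x \code{{2..6}} and
#' collapses them modulo the ring-swap and per-ring mirror symmetries.
#' With at least one bromine there are exactly 209 distinct congeners
#' (the classical PBDE congener count).
#'
#' @param include_unsubstituted Keep the bare diphenyl ether (zero
#'   bromines)?  Default \code{FALSE}.
#' @return A list of \code{congener_spec} objects, unique by canonical
#'   name.
#' @export
enumerate_congeners <- function(include_unsubstituted = FALSE) {
  positions <- 2:6
  subsets <- lapply(0:31, function(mask) positions[bitwAnd(mask, 2^(0:4)) > 0L])
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (a in subsets) {
    for (b in subsets) {
      if (!include_unsubstituted && length(a) + length(b) == 0L) next
      sp <- congener_spec(a, b)
      if (is.null(seen[[sp$name]])) {
        seen[[sp$name]] <- TRUE
        out[[length(out) + 1L]] <- sp
      }
    }
  }
  out
}
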