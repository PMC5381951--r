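#' Hydrophobicity-to-channel-interaction anchor points
#'
#' The channel-interaction coefficients \eqn{\lambda^o} (open gate) and
#' \eqn{\lambda^c} (closed gate) of a bead are obtained by piecewise-linear
#' interpolation in its transfer free energy `g` between four anchor
#' substrates: the LLL tripeptide (most attractive channel interaction,
#' \eqn{\lambda = 1}), the QQQ tripeptide with helix and with coil backbone
#' (intermediate, fitted against reference translocation PMFs), and the DDD
#' tripeptide (most repulsive, \eqn{\lambda = 0}).
#'
#' The two QQQ anchor \eqn{\lambda} values are free parameters of the model;
#' the defaults here were fixed once against the packaged reference curves
#' and can be overridden.
#'
#' @param lambda_qqq_helix,lambda_qqq_coil length-2 numeric vectors
#'   `c(open, closed)` for the two intermediate anchors.
#' @return A tibble with columns `substrate`, `g`, `lambda_open`,
#'   `lambda_closed`, ordered by increasing `g`.
#' @examples
#' lambda_anchors()
#' @export
lambda_anchors <- function(lambda_qqq_helix = c(0.60, 0.55),
                           lambda_qqq_coil = c(0.35, 0.30)) {
  stopifnot(length(lambda_qqq_helix) == 2, length(lambda_qqq_coil) == 2)
  tibble(
    substrate = c("LLL", "QQQ_helix", "QQQ_coil", "DDD"),
    g = c(-6.1, 3.8, 9.1, 23.1),
    lambda_open = c(1, lambda_qqq_helix[1], lambda_qqq_coil[1], 0),
    lambda_closed = c(1, lambda_qqq_helix[2], lambda_qqq_coil[2], 0)
  )
}

#' Interpolate channel-interaction coefficients from bead hydrophobicity
#'
#' Piecewise-linear interpolation of \eqn{\lambda^o(g)} and
#' \eqn{\lambda^c(g)} through the four anchors of [lambda_anchors()].
#' Outside the anchor range the values are clamped to the endpoint values:
#' the LLL and DDD interactions are the most attractive and most repulsive
#' channel interactions the model admits.
#'
#' @param g numeric vector of bead transfer free energies in \eqn{\epsilon}.
#' @param anchors anchor table from [lambda_anchors()].
#' @return A tibble with columns `g`, `lambda_open`, `lambda_closed`.
#' @examples
#' lambda_interp(c(-6.1, 0, 23.1))
#' @export
lambda_interp <- function(g, anchors = lambda_anchors()) {
  stopifnot(all(is.finite(g)))
  tibble(
    g = g,
    lambda_open = stats::approx(anchors$g, anchors$lambda_open, xout = g,
                                rule = 2)$y,
    lambda_closed = stats::approx(anchors$g, anchors$lambda_closed, xout = g,
                                  rule = 2)$y
  )
}

#' Sign charge of a translocon residue triplet
#'
#' Fixed translocon (and ribosome protein) beads carry the *sign* of the
#' summed formal charge of their residue triplet: +1 if net positive, -1 if
#' net negative, 0 otherwise. Arginine and lysine count +1, aspartate and
#' glutamate -1; histidine is neutral. This differs from nascent-chain
#' beads, which keep the full charge sum.
#'
#' @param triplet character vector of 1-3 letter residue strings.
#' @return integer vector in \{-1, 0, +1\}.
#' @examples
#' translocon_triplet_charge(c("RKA", "DEK", "AAA"))
#' @export
translocon_triplet_charge <- function(triplet) {
  vapply(strsplit(toupper(triplet), ""), function(res) {
    as.integer(sign(sum(residue_charge(res))))
  }, integer(1))
}

# split 1:n into triplet groups starting at offset `frame` (0, 1 or 2);
# leftover residues at either end form short terminal groups
.frame_groups <- function(n, frame) {
  stopifnot(frame %in% 0:2)
  starts <- if (frame == 0) seq(1, n, by = 3) else c(1, seq(frame + 1, n, by = 3))
  lapply(seq_along(starts), function(i) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1 else n
    seq(from, min(to, n))
  })
}

#' Map an amino-acid sequence to coarse-grained beads
#'
#' Groups the sequence into consecutive residue triplets (3:1 mapping) and
#' assigns each bead its water-membrane transfer free energy `g` (sum of the
#' per-residue values, with the 1.78 \eqn{\epsilon} coil penalty for each
#' non-hydrogen-bonded residue), its charge `q` (sum of formal residue
#' charges), and its channel-interaction coefficients
#' \eqn{\lambda^o, \lambda^c} via [lambda_interp()].
#'
#' The N- and C-terminal beads receive an additional +1 and -1 charge,
#' respectively, and 6 \eqn{\epsilon} is added to their transfer free
#' energies to account for the charged termini.
#'
#' @param aa_seq amino-acid sequence: a single string or a character vector
#'   of one-letter codes.
#' @param ss_string secondary-structure assignment of the same length:
#'   `"C"` marks coil; every other letter (`"H"`, `"E"`, ...) is treated as
#'   hydrogen-bonded backbone.
#' @param frame triplet-grouping offset, 0, 1 or 2. Frames 1 and 2 leave a
#'   short (1-2 residue) terminal bead at the N-terminus rather than dropping
#'   residues, so chain length and total charge are conserved.
#' @param anchors anchor table from [lambda_anchors()].
#' @param constants constants list from [sec_constants()].
#' @return A tibble with one row per bead: `index`, `frame`, `triplet`, `ss`,
#'   `res_start`, `res_end`, `g` (\eqn{\epsilon}), `q` (integer),
#'   `lambda_open`, `lambda_closed`.
#' @examples
#' map_sequence("LLLLLLLLL", "HHHHHHHHH")
#' @export
map_sequence <- function(aa_seq, ss_string, frame = 0,
                         anchors = lambda_anchors(),
                         constants = sec_constants()) {
  aa <- .as_residue_vector(aa_seq)
  ss <- .as_residue_vector(ss_string)
  if (length(aa) == 0) abort("empty sequence")
  if (length(ss) != length(aa)) {
    abort("secondary-structure string must match sequence length")
  }
  if (length(aa) < 3) abort("sequence too short to form a bead triplet")
  is_helix <- toupper(ss) != "C"
  groups <- .frame_groups(length(aa), frame)

  beads <- purrr::map_dfr(seq_along(groups), function(i) {
    idx <- groups[[i]]
    tibble(
      index = i,
      frame = as.integer(frame),
      triplet = paste(aa[idx], collapse = ""),
      ss = paste(toupper(ss[idx]), collapse = ""),
      res_start = idx[1],
      res_end = idx[length(idx)],
      g = sum(residue_tfe(aa[idx], is_helix[idx], constants)),
      q = sum(residue_charge(aa[idx]))
    )
  })
  n <- nrow(beads)
  beads$q[1] <- beads$q[1] + 1L
  beads$q[n] <- beads$q[n] - 1L
  beads$g[c(1, n)] <- beads$g[c(1, n)] + constants$terminal_penalty
  lam <- lambda_interp(beads$g, anchors)
  beads$lambda_open <- lam$lambda_open
  beads$lambda_closed <- lam$lambda_closed
  beads
}

.as_residue_vector <- function(x) {
  if (length(x) == 1) strsplit(x, "")[[1]] else as.character(x)
}

#' Enumerate the three frameshifted bead representations
#'
#' The 3:1 residue-to-bead mapping admits three groupings of the same
#' sequence (frameshifts 0, 1 and 2). Assay results are averaged over the
#' three downstream, since no frame is privileged.
#'
#' @inheritParams map_sequence
#' @return A list of three bead tibbles (frames 0, 1, 2).
#' @examples
#' frames <- enumerate_frameshifts(strrep("A", 12), strrep("H", 12))
#' vapply(frames, nrow, integer(1))
#' @export
enumerate_frameshifts <- function(aa_seq, ss_string,
                                  anchors = lambda_anchors(),
                                  constants = sec_constants()) {
  aa <- .as_residue_vector(aa_seq)
  if (length(aa) < 5) abort("sequence too short to enumerate frameshifts")
  lapply(0:2, function(f) {
    map_sequence(aa_seq, ss_string, frame = f, anchors = anchors,
                 constants = constants)
  })
}

#' Read a sequence and secondary-structure pair from files
#'
#' @param fasta path to a FASTA file; the first record is used.
#' @param ss path to a plain-text file whose non-comment, non-header lines
#'   concatenate to a secondary-structure string of the same length
#'   (characters H/C/E).
#' @return A list with elements `aa` and `ss` (single strings).
#' @export
read_sequence <- function(fasta, ss) {
  recs <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE)
  aa <- toupper(as.character(recs[[1]]))
  lines <- readLines(ss)
  lines <- lines[!grepl("^[#>]", lines)]
  ss_str <- toupper(gsub("\\s", "", paste(lines, collapse = "")))
  if (nchar(ss_str) != nchar(aa)) {
    abort("secondary-structure string must match sequence length")
  }
  list(aa = aa, ss = ss_str)
}

#' Write a bead table to TSV
#'
#' @param beads bead tibble from [map_sequence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bead_table <- function(beads, path) {
  out <- beads[, c("index", "triplet", "ss", "g", "q",
                   "lambda_open", "lambda_closed", "frame")]
  names(out)[names(out) == "g"] <- "g_eps"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
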