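#' Assemble a simulation geometry
#'
#' Builds the fixed simulation scaffold: translocon channel beads in their
#' closed and open lateral-gate conformations, ribosome beads (identical for
#' both conformations), the implicit-membrane region, the translation
#' insertion point, and the repulsive sphere standing in for the
#' non-explicit part of the ribosome.
#'
#' Coordinates are in \eqn{\sigma}; the origin is the geometric centre of the
#' channel beads, the membrane spans the x-y plane with midplane z = 0, +z is
#' the cytosolic (ribosomal) side and z below the membrane slab the lumenal
#' side.
#'
#' @param beads a data frame with columns `id`, `group` ("channel" or
#'   "ribosome"), `conformation` ("closed", "open", or "both" for ribosome
#'   beads), `x`, `y`, `z` (\eqn{\sigma}), `charge` (-1/0/+1), `class`
#'   ("normal"/"confined" for channel, "ribosome" otherwise), `exterior`
#'   (logical metadata flag).
#' @param membrane list with `radius` (channel cylinder radius, 1.5),
#'   `half_width` (slab half-width, 2) and `switch_width` (0.25), all
#'   \eqn{\sigma}.
#' @param insertion_point length-3 numeric, the ribosome exit-tunnel mouth
#'   where new beads appear (default (0, 0, 3.4), at the ribosome exit
#'   tunnel mouth just above the channel).
#' @param sphere_center length-3 numeric, centre of the repulsive sphere
#'   (default (-10, -0.5, 1)).
#' @param sphere_enabled logical; disable to simulate without the implicit
#'   ribosome body (used for free-chain reference systems).
#' @return An object of class `sec_geometry`.
#' @export
sec_geometry <- function(beads,
                         membrane = list(radius = 1.5, half_width = 2,
                                         switch_width = 0.25),
                         insertion_point = c(0, 0, 3.4),
                         sphere_center = c(-10, -0.5, 1),
                         sphere_enabled = TRUE) {
  beads <- as_tibble(beads)
  req <- c("id", "group", "conformation", "x", "y", "z", "charge", "class",
           "exterior")
  missing_cols <- setdiff(req, names(beads))
  if (length(missing_cols)) {
    abort(paste0("geometry table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  closed <- beads[beads$group == "channel" & beads$conformation == "closed", ]
  open_ <- beads[beads$group == "channel" & beads$conformation == "open", ]
  closed <- closed[order(closed$id), ]
  open_ <- open_[order(open_$id), ]
  if (nrow(closed) != nrow(open_)) {
    abort("closed and open conformations must have equal channel bead counts")
  }
  if (nrow(closed) && (!identical(closed$charge, open_$charge) ||
                       !identical(closed$class, open_$class))) {
    abort("channel bead charges and classes must be identical across conformations")
  }
  structure(
    list(beads = beads, membrane = membrane,
         insertion_point = as.numeric(insertion_point),
         sphere_center = as.numeric(sphere_center),
         sphere_enabled = isTRUE(sphere_enabled)),
    class = "sec_geometry"
  )
}

#' @export
print.sec_geometry <- function(x, ...) {
  n_ch <- sum(x$beads$group == "channel" & x$beads$conformation == "closed")
  n_rb <- sum(x$beads$group == "ribosome")
  cat("<sec_geometry>", n_ch, "channel beads (two conformations),",
      n_rb, "ribosome beads\n")
  cat("  membrane: cylinder radius", x$membrane$radius, "sigma, slab half-width",
      x$membrane$half_width, "sigma\n")
  cat("  insertion point:", paste(x$insertion_point, collapse = ", "), "\n")
  invisible(x)
}

# matrices for the C++ kernels
.geom_matrices <- function(geom) {
  b <- geom$beads
  closed <- b[b$group == "channel" & b$conformation == "closed", ]
  open_ <- b[b$group == "channel" & b$conformation == "open", ]
  closed <- closed[order(closed$id), ]
  open_ <- open_[order(open_$id), ]
  ribo <- b[b$group == "ribosome", ]
  list(
    ch_closed = as.matrix(closed[, c("x", "y", "z")]),
    ch_open = as.matrix(open_[, c("x", "y", "z")]),
    ch_q = as.numeric(closed$charge),
    ch_conf = as.integer(closed$class == "confined"),
    ribo = as.matrix(ribo[, c("x", "y", "z")]),
    ribo_q = as.numeric(ribo$charge),
    membrane = as.numeric(c(geom$membrane$radius, geom$membrane$half_width,
                            geom$membrane$switch_width)),
    insertion = geom$insertion_point,
    sphere = geom$sphere_center,
    sphere_enabled = as.integer(geom$sphere_enabled)
  )
}

#' Implicit-membrane characteristic function
#'
#' Smooth indicator \eqn{S_{mem}(x) = [1 - S(x, y)]\,S(z)} of the implicit
#' membrane: approximately 1 inside the membrane slab but outside the channel
#' cylinder, and 0 elsewhere. `S(x, y)` and `S(z)` are products of tanh
#' switching functions with width 0.25 \eqn{\sigma}.
#'
#' @param x,y,z numeric vectors of coordinates in \eqn{\sigma}; `x` may also
#'   be an n-by-3 matrix.
#' @param membrane membrane parameter list (see [sec_geometry()]).
#' @return numeric vector in \[0, 1\].
#' @examples
#' membrane_indicator(0, 0, 0)    # channel lumen: ~0
#' membrane_indicator(4, 0, 0)    # membrane core: ~1
#' @export
membrane_indicator <- function(x, y = NULL, z = NULL,
                               membrane = list(radius = 1.5, half_width = 2,
                                               switch_width = 0.25)) {
  if (is.matrix(x)) {
    y <- x[, 2]; z <- x[, 3]; x <- x[, 1]
  }
  w <- membrane$switch_width
  rho <- sqrt(x^2 + y^2)
  sxy <- 0.25 * (1 + tanh((rho + membrane$radius) / w)) *
    (1 - tanh((rho - membrane$radius) / w))
  sz <- 0.25 * (1 + tanh((z + membrane$half_width) / w)) *
    (1 - tanh((z - membrane$half_width) / w))
  (1 - sxy) * sz
}

#' Map an ordered protein backbone to coarse-grained beads
#'
#' Consecutive residue triplets are mapped to one bead at the centroid of
#' their C-alpha positions (3:1 mapping); a trailing partial triplet forms a
#' final bead from the remaining residues. Bead charges are the *sign* of
#' the triplet formal-charge sum ([translocon_triplet_charge()]).
#'
#' @param coords n-by-3 numeric matrix of C-alpha coordinates, ordered by
#'   primary sequence.
#' @param sequence amino-acid sequence (string or character vector) of
#'   length n.
#' @return A tibble with columns `index`, `triplet`, `x`, `y`, `z`, `charge`.
#' @export
map_protein_to_beads <- function(coords, sequence) {
  coords <- as.matrix(coords)
  aa <- .as_residue_vector(sequence)
  if (nrow(coords) != length(aa)) {
    abort("coordinate and sequence lengths differ")
  }
  groups <- .frame_groups(length(aa), 0)
  purrr::map_dfr(seq_along(groups), function(i) {
    idx <- groups[[i]]
    ctr <- unname(colMeans(coords[idx, , drop = FALSE]))
    trip <- paste(aa[idx], collapse = "")
    tibble(index = i, triplet = trip, x = ctr[1], y = ctr[2], z = ctr[3],
           charge = translocon_triplet_charge(trip))
  })
}

#' Map ribosomal RNA nucleotides to coarse-grained beads
#'
#' Each nucleotide is mapped to two beads, one at the centroid of its
#' sugar-phosphate backbone atoms (charge -1) and one at the centroid of its
#' base atoms (neutral).
#'
#' @param atoms a data frame with columns `nucleotide` (identifier), `part`
#'   ("backbone" or "base"), and `x`, `y`, `z`.
#' @return A tibble with columns `nucleotide`, `part`, `x`, `y`, `z`,
#'   `charge`; two rows per nucleotide.
#' @export
map_rna_to_beads <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    return(tibble(nucleotide = character(), part = character(),
                  x = numeric(), y = numeric(), z = numeric(),
                  charge = numeric()))
  }
  if (!all(c("backbone", "base") %in% unique(atoms$part))) {
    abort("each nucleotide needs both backbone and base atom groups")
  }
  out <- atoms |>
    group_by(.data$nucleotide, .data$part) |>
    summarise(x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
              .groups = "drop")
  counts <- table(out$nucleotide)
  if (any(counts != 2)) {
    abort("each nucleotide needs both backbone and base atom groups")
  }
  out$charge <- ifelse(out$part == "backbone", -1, 0)
  out
}

#' Align a raw geometry to the model coordinate conventions
#'
#' Applies one rigid transform to both channel conformations and the
#' ribosome so that (i) the origin sits at the geometric centre of the
#' closed-conformation channel beads and (ii) the midpoint of the
#' lateral-gate (LG) beads in the open conformation lies on the +y axis
#' (x = 0, y > 0). The channel axis is assumed to be along z in the input.
#'
#' @param geom a `sec_geometry`.
#' @param lg_ids integer vector of channel bead `id`s belonging to the two
#'   lateral-gate helices.
#' @return The transformed `sec_geometry`.
#' @export
align_and_center <- function(geom, lg_ids) {
  b <- geom$beads
  closed <- b$group == "channel" & b$conformation == "closed"
  ctr <- colMeans(as.matrix(b[closed, c("x", "y", "z")]))
  b$x <- b$x - ctr[1]; b$y <- b$y - ctr[2]; b$z <- b$z - ctr[3]
  lg <- b$group == "channel" & b$conformation == "open" & b$id %in% lg_ids
  if (!any(lg)) abort("no lateral-gate beads found for the given ids")
  mid <- colMeans(as.matrix(b[lg, c("x", "y")]))
  r <- sqrt(sum(mid^2))
  if (r < 1e-8) abort("degenerate lateral-gate definition: midpoint on the axis")
  theta <- pi / 2 - atan2(mid[2], mid[1])
  ct <- cos(theta); st <- sin(theta)
  xr <- ct * b$x - st * b$y
  yr <- st * b$x + ct * b$y
  b$x <- xr; b$y <- yr
  geom$beads <- b
  geom
}

# run code with a private RNG stream, restoring global state afterwards
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic channel and ribosome geometry fixture
#'
#' Builds a deterministic hourglass-shaped stack of channel bead rings
#' spanning the membrane slab, with pore-lining beads of the central
#' constriction ring marked `confined`, plus a small ribosome collar around
#' the translation insertion point. The open conformation displaces the two
#' bead columns facing the +y axis (the lateral gate) outward, creating a
#' lateral path from the pore to the membrane; bead counts, charges and
#' classes are identical across conformations.
#'
#' This is a self-contained stand-in geometry for testing and examples; it
#' is not derived from an experimental translocon structure.
#'
#' @param seed integer seed controlling the small deterministic coordinate
#'   jitter; the same seed always yields the same geometry.
#' @param n_rings odd number of channel rings spanning the slab (default 5).
#' @param pore_radius radius of the central constriction ring in
#'   \eqn{\sigma} (default 1.31).
#' @param open_dilation radial dilation of the constriction ring in the
#'   open conformation (\eqn{\sigma}, default 0): by default the
#'   constriction beads sit at identical positions in both conformations,
#'   so the open/closed difference in pore energetics comes entirely from
#'   the per-conformation interaction parameters, as in the channel
#'   parameter table.
#' @param beads_per_ring beads per channel ring (default 8).
#' @return A `sec_geometry`.
#' @examples
#' geom <- synthetic_channel_fixture()
#' geom
#' @export
synthetic_channel_fixture <- function(seed = 1, n_rings = 5,
                                      pore_radius = 1.31,
                                      open_dilation = 0,
                                      beads_per_ring = 8) {
  stopifnot(n_rings >= 3, n_rings %% 2 == 1, pore_radius > 0)
  zs <- seq(-2, 2, length.out = n_rings)
  mid <- (n_rings + 1) / 2
  k <- seq_len(beads_per_ring) - 1

  jitter_tbl <- .with_seed(seed, {
    matrix(runif(n_rings * beads_per_ring * 2, -0.03, 0.03),
           ncol = 2)
  })

  rows <- list()
  id <- 0
  rad_prof <- function(az) pore_radius + 0.55 * pmin(az, 2)
  # constriction-ring angles: a seam pair facing the +y lateral gate that
  # swings aside (and slightly outward) in the open conformation, plus
  # four sealing beads around the rest of the ring
  conf_ang_closed <- c(75, 105, 210, 330) * pi / 180
  conf_ang_open <- c(25, 155, 210, 330) * pi / 180
  for (ri in seq_len(n_rings)) {
    confined <- ri == mid
    radius <- rad_prof(abs(zs[ri]))
    nb <- if (confined) length(conf_ang_closed) else beads_per_ring
    ang <- if (confined) conf_ang_closed else
      ((seq_len(nb) - 1) * 360 / nb + 11.25) * pi / 180
    for (j in seq_len(nb)) {
      id <- id + 1
      jx <- if (confined) 0 else jitter_tbl[(ri - 1) * beads_per_ring + j, 1]
      jz <- if (confined) 0 else jitter_tbl[(ri - 1) * beads_per_ring + j, 2]
      stopifnot(!confined || nb <= beads_per_ring)
      a_cl <- ang[j]
      r_cl <- radius
      # lateral gate: the two columns facing +y, displaced when open
      # lateral-gate columns: only the rings away from the constriction
      # open, leaving a wide path from pore to membrane on the +y side
      is_gate <- !confined && j %in% c(2, 3) && abs(zs[ri]) >= 1
      a_op <- a_cl
      r_op <- r_cl
      if (is_gate) {
        a_op <- a_cl + (if (j == 2) -30 else 30) * pi / 180
        r_op <- r_cl + 1.2
      }
      if (confined) {
        r_op <- r_cl + open_dilation
        a_op <- conf_ang_open[j]
        if (j <= 2) r_op <- r_cl + 0.4  # seam pair also moves outward
      }
      charge <- 0
      if (ri == n_rings && j == 5) charge <- 1
      if (ri == n_rings && j == 1) charge <- -1
      if (ri == 1 && j == 3) charge <- 1
      if (ri == 1 && j == 7) charge <- -1
      for (conf in c("closed", "open")) {
        a <- if (conf == "open") a_op else a_cl
        r <- if (conf == "open") r_op else r_cl
        rows[[length(rows) + 1]] <- tibble(
          id = id, group = "channel", conformation = conf,
          x = r * cos(a) + jx, y = r * sin(a), z = zs[ri] + jz,
          charge = charge,
          class = if (confined) "confined" else "normal",
          exterior = !confined
        )
      }
    }
  }

  # ribosome: an exit-tunnel collar around the insertion point plus a
  # partial shield arc that funnels emerging beads toward the channel
  # mouth while leaving a window on the +y (lateral-gate) side for
  # cytosolic loops
  collar_ang <- (k * 45) * pi / 180
  for (j in seq_len(beads_per_ring)) {
    id <- id + 1
    rows[[length(rows) + 1]] <- tibble(
      id = id, group = "ribosome", conformation = "both",
      x = 1.9 * cos(collar_ang[j]), y = 1.9 * sin(collar_ang[j]), z = 4.2,
      charge = if (j %% 2 == 0) -1 else 0,
      class = "ribosome", exterior = TRUE
    )
  }
  # tunnel plug above the insertion point: the exit tunnel is filled by
  # the (implicit) ribosome behind the emerging chain
  plug <- rbind(c(0, 0, 5.3),
                cbind(0.95 * cos((0:3) * pi / 2), 0.95 * sin((0:3) * pi / 2),
                      4.9))
  for (j in seq_len(nrow(plug))) {
    id <- id + 1
    rows[[length(rows) + 1]] <- tibble(
      id = id, group = "ribosome", conformation = "both",
      x = plug[j, 1], y = plug[j, 2], z = plug[j, 3],
      charge = 0, class = "ribosome", exterior = TRUE
    )
  }
  shield_ang <- seq(112.5, 292.5, by = 45) * pi / 180
  for (j in seq_along(shield_ang)) {
    id <- id + 1
    rows[[length(rows) + 1]] <- tibble(
      id = id, group = "ribosome", conformation = "both",
      x = 2.1 * cos(shield_ang[j]), y = 2.1 * sin(shield_ang[j]), z = 2.8,
      charge = if (j == 3) -1 else 0,
      class = "ribosome", exterior = TRUE
    )
  }
  # the underside of the ribosome body: a bead roof over the vestibule so
  # the emerging chain stays between ribosome and membrane instead of
  # diffusing away above the exit tunnel
  for (rr in c(3.1, 4.3, 5.5)) {
    nb <- round(2 * pi * rr / 1.3)
    for (j in seq_len(nb)) {
      id <- id + 1
      a <- (j - 0.5) * 2 * pi / nb
      rows[[length(rows) + 1]] <- tibble(
        id = id, group = "ribosome", conformation = "both",
        x = rr * cos(a), y = rr * sin(a), z = 4.6,
        charge = 0, class = "ribosome", exterior = TRUE
      )
    }
  }

  beads <- bind_rows(rows)
  # recentre so the origin is the channel-bead centroid exactly
  closed <- beads$group == "channel" & beads$conformation == "closed"
  ctr <- colMeans(as.matrix(beads[closed, c("x", "y", "z")]))
  beads$x <- beads$x - ctr[1]; beads$y <- beads$y - ctr[2]
  beads$z <- beads$z - ctr[3]
  sec_geometry(beads)
}

#' Write and read geometry tables
#'
#' Flat TSV serialization of the bead table plus a header of key-value
#' comment lines holding the membrane, insertion-point and sphere
#' parameters. Coordinates are written at full double precision, so a
#' write-read round trip reproduces the geometry bit-exactly.
#'
#' @param geom a `sec_geometry`.
#' @param path file path.
#' @return `write_geometry()` returns `path` invisibly; `read_geometry()`
#'   returns a `sec_geometry`.
#' @export
write_geometry <- function(geom, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  writeLines(c(
    sprintf("# membrane\t%s", num(c(geom$membrane$radius,
                                    geom$membrane$half_width,
                                    geom$membrane$switch_width))),
    sprintf("# insertion_point\t%s", num(geom$insertion_point)),
    sprintf("# sphere_center\t%s", num(geom$sphere_center)),
    sprintf("# sphere_enabled\t%d", as.integer(geom$sphere_enabled))
  ), con)
  b <- geom$beads
  writeLines(paste(c("id", "group", "conformation", "x", "y", "z",
                     "charge", "class", "exterior"), collapse = "\t"), con)
  writeLines(sprintf("%d\t%s\t%s\t%.17g\t%.17g\t%.17g\t%g\t%s\t%d",
                     b$id, b$group, b$conformation, b$x, b$y, b$z,
                     b$charge, b$class, as.integer(b$exterior)), con)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_field <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    as.numeric(strsplit(strsplit(ln, "\t")[[1]][2], ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  tab <- read.table(text = body, header = TRUE, sep = "\t",
                    colClasses = c("integer", "character", "character",
                                   "numeric", "numeric", "numeric",
                                   "numeric", "character", "integer"))
  tab$exterior <- as.logical(tab$exterior)
  mem <- get_field("membrane")
  sec_geometry(
    as_tibble(tab),
    membrane = list(radius = mem[1], half_width = mem[2], switch_width = mem[3]),
    insertion_point = get_field("insertion_point"),
    sphere_center = get_field("sphere_center"),
    sphere_enabled = get_field("sphere_enabled") == 1
  )
}

#' Map a PDB structure to coarse-grained beads
#'
#' Reads C-alpha records from a PDB file (via the bio3d reader) and applies
#' the 3:1 triplet-centroid mapping of [map_protein_to_beads()]. Chains are
#' processed in file order and concatenated.
#'
#' @param path path to a PDB file.
#' @return A tibble as returned by [map_protein_to_beads()].
#' @export
read_pdb_beads <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB files requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  ca <- bio3d::atom.select(pdb, "calpha")
  atoms <- pdb$atom[ca$atom, ]
  aa1 <- bio3d::aa321(atoms$resid)
  keep <- aa1 %in% ww_scale()$residue
  map_protein_to_beads(as.matrix(atoms[keep, c("x", "y", "z")]), aa1[keep])
}
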