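#' Kabsch least-squares superposition
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD
#' between paired point sets, i.e. mapping `coords1` onto `coords2` as
#' `x' = R x + t`. Reflections are forbidden (the determinant sign is
#' corrected in the SVD), so the result is always a rigid motion.
#'
#' @param coords1,coords2 N x 3 coordinate matrices with matched rows
#'   (N >= 3, not all collinear).
#' @return An object of class `superposition` with elements `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Angstrom) and `n_pairs`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' kabsch_superpose(p, p)$rmsd
#' @export
kabsch_superpose <- function(coords1, coords2) {
  coords1 <- as.matrix(coords1); coords2 <- as.matrix(coords2)
  if (ncol(coords1) != 3 || ncol(coords2) != 3)
    abort("coordinate matrices must have 3 columns")
  n <- nrow(coords1)
  if (nrow(coords2) != n) abort("coordinate sets must have equal length")
  if (n < 3) abort("at least 3 point pairs are required")
  c1 <- colMeans(coords1); c2 <- colMeans(coords2)
  p <- sweep(coords1, 2, c1); q <- sweep(coords2, 2, c2)
  sv1 <- svd(p)$d
  if (sv1[2] < 1e-8 * max(sv1[1], 1))
    abort("degenerate (collinear) point set; superposition is not unique")
  h <- crossprod(p, q)            # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(c2 - rot %*% c1)
  moved <- p %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d pairs\n", x$rmsd,
              x$n_pairs))
  invisible(x)
}

#' @rdname quatstab-tidiers
#' @export
tidy.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
         det_rotation = det(x$rotation),
         translation_norm = sqrt(sum(x$translation^2)))
}

#' @rdname quatstab-tidiers
#' @export
glance.superposition <- tidy.superposition

#' Global sequence alignment
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and affine
#' gap cost (a gap of length L costs `gap_open + L * gap_extend`).
#' Traceback tie-breaks are deterministic: diagonal over gap in `seq1`
#' over gap in `seq2`. Identity is the percentage of matching aligned
#' columns.
#'
#' @param seq1,seq2 Non-empty one-letter character strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A list of class `seq_alignment`: `pairs` (tibble of aligned
#'   positions `pos1`, `pos2`, strictly increasing in both), `score`,
#'   `identity_pct`.
#' @examples
#' align_sequences("ACDEFG", "ACEFG")
#' @export
align_sequences <- function(seq1, seq2, match = 1, mismatch = 0,
                            gap_open = 5, gap_extend = 1) {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("sequences must be non-empty")
  res <- cpp_nw_align(seq1, seq2, match, mismatch, gap_open, gap_extend)
  pairs <- tibble(pos1 = res$pos1, pos2 = res$pos2)
  idn <- if (nrow(pairs) > 0) 100 * res$n_match / nrow(pairs) else 0
  structure(list(pairs = pairs, score = res$score, identity_pct = idn),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d aligned pairs, identity %.1f%%, score %g\n",
              nrow(x$pairs), x$identity_pct, x$score))
  invisible(x)
}

#' Exact fixed-radius neighbour search
#'
#' Returns exactly the cross-set atom pairs at Euclidean distance strictly
#' below `cutoff` (complete: a cell-list search verified against the
#' quadratic scan).
#'
#' @param atoms1,atoms2 Atom tibbles (with `x`, `y`, `z`) or N x 3 matrices.
#' @param cutoff Distance cutoff in Angstrom (> 0; strict inequality).
#' @return Tibble with columns `i`, `j` (row indices into the inputs) and
#'   `dist`.
#' @export
neighbor_pairs <- function(atoms1, atoms2, cutoff) {
  if (cutoff <= 0) abort("cutoff must be positive")
  m1 <- if (is.matrix(atoms1)) atoms1 else model_xyz(atoms1)
  m2 <- if (is.matrix(atoms2)) atoms2 else model_xyz(atoms2)
  res <- cpp_neighbor_pairs(m1, m2, cutoff)
  tibble(i = res$i, j = res$j, dist = res$dist)
}

#' Superpose two chains and report the RMSD over equivalent atoms
#'
#' Builds a residue correspondence between the chains, collects one named
#' atom per matched residue (Calpha by default) and calls
#' [kabsch_superpose()]. With `corr = "auto"`, chains with identical
#' coordinate-derived sequences are matched positionally via author residue
#' numbering restricted to residues resolved in both chains; otherwise a
#' global sequence alignment ([align_sequences()]) provides the
#' correspondence.
#'
#' @param chain1,chain2 Atom tibbles for single chains (see
#'   [model_chain()]).
#' @param atom Atom name to superpose on (default `"CA"`).
#' @param corr `"auto"` or a [align_sequences()]-style correspondence
#'   (list with a `pairs` tibble of residue indices).
#' @return A `superposition` object (see [kabsch_superpose()]).
#' @export
chain_rmsd <- function(chain1, chain2, atom = "CA", corr = "auto") {
  r1 <- chain_residue_table(chain1, atom)
  r2 <- chain_residue_table(chain2, atom)
  if (identical(corr, "auto")) {
    s1 <- paste(r1$letter, collapse = "")
    s2 <- paste(r2$letter, collapse = "")
    if (identical(s1, s2)) {
      # positional match on author numbering, shared resolved residues
      key1 <- paste(r1$resno, r1$insert)
      key2 <- paste(r2$resno, r2$insert)
      shared <- intersect(key1, key2)
      idx1 <- match(shared, key1)
      idx2 <- match(shared, key2)
    } else {
      al <- align_sequences(s1, s2)
      keep <- r1$letter[al$pairs$pos1] == r2$letter[al$pairs$pos2]
      idx1 <- al$pairs$pos1[keep]
      idx2 <- al$pairs$pos2[keep]
    }
  } else {
    pairs <- if (is.list(corr) && !is.null(corr$pairs)) corr$pairs else corr
    idx1 <- pairs$pos1
    idx2 <- pairs$pos2
  }
  ok <- !is.na(r1$x[idx1]) & !is.na(r2$x[idx2])
  idx1 <- idx1[ok]; idx2 <- idx2[ok]
  if (length(idx1) < 3)
    abort("fewer than 3 matched atoms; cannot superpose")
  kabsch_superpose(cbind(r1$x[idx1], r1$y[idx1], r1$z[idx1]),
                   cbind(r2$x[idx2], r2$y[idx2], r2$z[idx2]))
}

# one row per residue with the coordinates of the selected atom (NA when
# that atom is unresolved)
chain_residue_table <- function(chain, atom) {
  if (inherits(chain, "struct_model")) {
    ids <- chain_ids(chain)
    if (length(ids) != 1)
      abort("pass a single-chain model or an atom tibble")
    chain <- model_chain(chain, ids)
  }
  res <- chain |>
    distinct(.data$resno, .data$insert, .data$resname) |>
    arrange(.data$resno, .data$insert)
  sel <- chain |>
    filter(.data$elety == atom) |>
    distinct(.data$resno, .data$insert, .keep_all = TRUE) |>
    select("resno", "insert", "x", "y", "z")
  res <- left_join(res, sel, by = c("resno", "insert"))
  res$letter <- unname(AA_3TO1[res$resname])
  res$letter[is.na(res$letter)] <- "X"
  res
}
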