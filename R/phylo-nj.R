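#' Neighbour-joining tree from a distance matrix
#'
#' Classical neighbour joining (Saitou & Nei, with the usual Q-criterion):
#' repeatedly joins the pair minimising
#' `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)`, assigning branch lengths
#' `v_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))`. Ties are broken by joining the
#' lowest-index pair (row-major scan). Negative branch lengths are clamped
#' to zero with the deficit moved to the sibling branch. On an additive
#' matrix the tree's path metric reproduces the input exactly.
#'
#' @param d symmetric distance matrix with taxa dimnames; all entries must
#'   be finite (pre-filter or cap saturated pairs first).
#' @return an unrooted `phylo` tree (trifurcating root node).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stopf("nj_tree: at least 3 taxa are required")
  if (any(!is.finite(d))) stopf("nj_tree: non-finite distances; filter or cap saturated pairs")
  if (max(abs(d - t(d))) > 1e-12) stopf("nj_tree: matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  frag <- labels  # newick fragment per active cluster
  D <- d
  while (length(frag) > 3L) {
    r <- length(frag)
    R <- rowSums(D)
    best <- NULL; bestq <- Inf
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * D[i, j] - R[i] - R[j]
      if (q < bestq - 1e-12) { bestq <- q; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0; vi <- max(vi, 0) }
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
  }
  ## final three-way join, closed form
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(va), frag[2], fmt(vb),
                 frag[3], fmt(vc))
  ape::read.tree(text = txt)
}

#' Write / read Newick
#'
#' Serialisation wrappers (ape's parser underneath). Round trips preserve
#' topology, branch lengths (to `digits` decimals) and node support labels.
#'
#' @param tree a `phylo`.
#' @param path optional file path; when `NULL`, the Newick string is
#'   returned.
#' @param digits branch-length decimals retained (default 6).
#' @return `write_newick()`: the Newick string (invisibly when written to a
#'   file); `read_newick()`: a `phylo`.
#' @export
write_newick <- function(tree, path = NULL, digits = 6) {
  if (!is.null(tree$edge.length))
    tree$edge.length <- round(tree$edge.length, digits)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname write_newick
#' @param text Newick string or path to a Newick file.
#' @export
read_newick <- function(text) {
  tr <- tryCatch({
    if (length(text) == 1L && file.exists(text)) ape::read.tree(text)
    else ape::read.tree(text = text)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stopf("read_newick: malformed Newick input (near '%s')",
          substr(paste(text, collapse = ""), 1, 40))
  tr
}
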