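#' Directed networks with the cascade-model adjacency conventions
#'
#' An `infi_network` stores a directed graph as a dense 0/1 edge set over
#' integer node indices `1..N` together with the original node names.
#' Ingestion enforces the conventions used throughout the package: no
#' self-loops (the adjacency diagonal is identically zero, even when the
#' input lists a node acting on itself) and no duplicate parallel edges
#' (links are unweighted, so duplicates collapse to a single edge).
#'
#' @param edges a data frame (or two-column matrix) whose first two columns
#'   are source and target node names; extra columns (e.g. an interaction
#'   type) are ignored.
#' @param node_names optional character vector fixing the node universe and
#'   order; defaults to first-appearance order in `edges`. Nodes named here
#'   but absent from `edges` become isolated nodes.
#' @param quiet suppress the message reporting dropped self-loops/duplicates.
#' @return an object of class `infi_network` with fields `node_names`,
#'   `edges` (two-column integer matrix, source then target), `N`, `N_links`.
#' @examples
#' net <- infi_network(data.frame(from = c("a", "b", "a"), to = c("b", "c", "a")))
#' net$N_links # the a->a self-loop is dropped
#' @export
infi_network <- function(edges, node_names = NULL, quiet = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("`edges` needs at least two columns (source, target)")
  src <- as.character(edges[[1L]])
  dst <- as.character(edges[[2L]])
  if (anyNA(src) || anyNA(dst)) stop("missing node names in the edge table")
  if (is.null(node_names)) {
    node_names <- unique(c(rbind(src, dst)))
  } else {
    node_names <- as.character(node_names)
    if (anyDuplicated(node_names)) stop("`node_names` must be unique")
    unknown <- setdiff(unique(c(src, dst)), node_names)
    if (length(unknown) > 0L) {
      stop("edge table references nodes absent from `node_names`: ",
           paste(head(unknown, 5L), collapse = ", "))
    }
  }
  i_src <- match(src, node_names)
  i_dst <- match(dst, node_names)
  self <- i_src == i_dst
  em <- cbind(source = i_src[!self], target = i_dst[!self])
  dup <- duplicated(em[, 1L] + (em[, 2L] - 1) * (length(node_names) + 1))
  n_dropped <- sum(self) + sum(dup)
  em <- em[!dup, , drop = FALSE]
  if (!quiet && n_dropped > 0L) {
    message("dropped ", sum(self), " self-loop(s) and ", sum(dup),
            " duplicate edge(s)")
  }
  structure(
    list(node_names = node_names, edges = em,
         N = length(node_names), N_links = nrow(em)),
    class = "infi_network"
  )
}

#' @export
print.infi_network <- function(x, ...) {
  cat("<infi_network> ", x$N, " nodes, ", x$N_links,
      " directed links (no self-loops, unweighted)\n", sep = "")
  invisible(x)
}

#' @describeIn infi_network edge table as a tibble of node names.
#' @param x an `infi_network`.
#' @param ... unused.
#' @export
tidy.infi_network <- function(x, ...) {
  tibble::tibble(source = x$node_names[x$edges[, 1L]],
                 target = x$node_names[x$edges[, 2L]])
}

#' Read a directed network from an edge-list or SIF file
#'
#' Edge-list format: two or three whitespace/tab-separated columns
#' (source, target, optional interaction type, ignored); lines starting with
#' `#` are comments. SIF format: `source relation target [target2 ...]`;
#' the relation token is ignored and multi-target lines expand to one edge
#' per target. Self-loops and duplicate edges are dropped on ingestion.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"sif"`.
#' @param quiet suppress the dropped-edge message.
#' @return an [infi_network].
#' @export
read_edge_list <- function(path, format = c("tsv", "sif"), quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge file: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  pairs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    tk <- toks[[k]]
    if (format == "tsv") {
      if (length(tk) < 2L || length(tk) > 3L) {
        stop("malformed edge record at line ", idx[k], " of ", path)
      }
      pairs[[k]] <- cbind(tk[1L], tk[2L])
    } else {
      if (length(tk) < 3L) {
        stop("malformed SIF record at line ", idx[k], " of ", path)
      }
      pairs[[k]] <- cbind(tk[1L], tk[3:length(tk)])
    }
  }
  em <- do.call(rbind, pairs)
  infi_network(data.frame(source = em[, 1L], target = em[, 2L],
                          stringsAsFactors = FALSE), quiet = quiet)
}

#' Write a network as canonical two-column TSV
#'
#' @param net an [infi_network].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "infi_network"))
  df <- tidy(net)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Invert all link directions
#'
#' Every edge j -> i becomes i -> j. Applying twice returns the original
#' edge set; PageRank of the inverted network is the CheiRank of the
#' original one.
#'
#' @param net an [infi_network].
#' @return an [infi_network] with the same nodes and reversed edges.
#' @export
invert_network <- function(net) {
  stopifnot(inherits(net, "infi_network"))
  net$edges <- net$edges[, c(2L, 1L), drop = FALSE]
  colnames(net$edges) <- c("source", "target")
  net
}

#' Panels of permanently fixed activator and repairing nodes
#'
#' A node panel designates the nodes whose spins are pinned for a whole
#' simulation: `red` nodes are pinned to +1 (activated state) and `blue`
#' nodes to -1 (repairing state). The two sets must be disjoint and every
#' panel node must exist in the network.
#'
#' @param net an [infi_network].
#' @param red,blue character node names or integer node indices.
#' @param labels optional named character vector of group tags.
#' @return an object of class `infi_panel` with integer index fields
#'   `fixed_red` and `fixed_blue`.
#' @export
node_panel <- function(net, red, blue, labels = NULL) {
  stopifnot(inherits(net, "infi_network"))
  as_idx <- function(x, what) {
    if (is.character(x)) {
      i <- match(x, net$node_names)
      if (anyNA(i)) stop(what, " panel names not in network: ",
                         paste(x[is.na(i)], collapse = ", "))
      i
    } else {
      i <- as.integer(x)
      if (any(i < 1L | i > net$N)) stop(what, " panel index out of range")
      i
    }
  }
  r <- as_idx(red, "red")
  b <- as_idx(blue, "blue")
  if (anyDuplicated(c(r, b))) stop("red and blue panels must be disjoint")
  structure(list(fixed_red = r, fixed_blue = b, labels = labels,
                 node_names = net$node_names),
            class = "infi_panel")
}

#' @export
print.infi_panel <- function(x, ...) {
  cat("<infi_panel> ", length(x$fixed_red), " fixed red (+1), ",
      length(x$fixed_blue), " fixed blue (-1)\n", sep = "")
  invisible(x)
}

#' Read a panel file (TSV: name, role, optional group label)
#'
#' @param path TSV file with columns name, role (`red` or `blue`) and an
#'   optional group label; `#` comment lines allowed.
#' @param net the [infi_network] the panel refers to.
#' @return an [node_panel()] object.
#' @export
read_panel <- function(path, net) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty panel file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  nm <- vapply(toks, `[`, "", 1L)
  role <- vapply(toks, `[`, "", 2L)
  if (length(role) > 1L && !role[1L] %in% c("red", "blue")) {
    # header row
    nm <- nm[-1L]
    role <- role[-1L]
    toks <- toks[-1L]
  }
  if (!all(role %in% c("red", "blue"))) {
    stop("panel roles must be 'red' or 'blue'")
  }
  lab <- vapply(toks, function(t) if (length(t) >= 3L) t[3L] else NA_character_, "")
  labels <- if (all(is.na(lab))) NULL else setNames(lab, nm)
  node_panel(net, red = nm[role == "red"], blue = nm[role == "blue"],
             labels = labels)
}

#' Build the Markov transition matrices of a directed network
#'
#' Constructs, as sparse matrices: the adjacency indicator `A` with
#' `A[i, j] = 1` iff there is an edge j -> i and a zero diagonal; the
#' column-normalised matrix `S_tilde` with `S_tilde[i, j] = A[i, j] / k_out(j)`
#' and all-zero columns at dangling nodes (no outgoing links); the
#' column-stochastic `S` equal to `S_tilde` except that dangling columns are
#' replaced by the uniform value `1/N`; and the symmetric coupling
#' `W = S_tilde + t(S_tilde)` that drives the spin dynamics. The spin
#' dynamics always use `S_tilde`/`W`; the dangling fix exists only in `S`,
#' which feeds the Google-matrix ranking.
#'
#' @param net an [infi_network].
#' @return an object of class `infi_matrices` with fields `A`, `S_tilde`,
#'   `S`, `W`, logical `dangling`, `N` and `node_names`.
#' @export
build_transition_matrices <- function(net) {
  stopifnot(inherits(net, "infi_network"))
  N <- net$N
  A <- Matrix::sparseMatrix(i = net$edges[, 2L], j = net$edges[, 1L],
                            x = 1, dims = c(N, N))
  out_deg <- Matrix::colSums(A)
  dangling <- out_deg == 0
  inv_deg <- ifelse(dangling, 0, 1 / out_deg)
  S_tilde <- A %*% Matrix::Diagonal(N, inv_deg)
  S <- S_tilde
  if (any(dangling) && N > 0L) {
    jd <- which(dangling)
    S <- S + Matrix::sparseMatrix(
      i = rep(seq_len(N), times = length(jd)),
      j = rep(jd, each = N),
      x = 1 / N, dims = c(N, N)
    )
  }
  W <- S_tilde + Matrix::t(S_tilde)
  as_dgc <- function(m) methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  structure(
    list(A = as_dgc(A), S_tilde = as_dgc(S_tilde), S = as_dgc(S),
         W = as_dgc(W), dangling = dangling, N = N,
         node_names = net$node_names),
    class = "infi_matrices"
  )
}

#' @export
print.infi_matrices <- function(x, ...) {
  cat("<infi_matrices> N = ", x$N, ", dangling nodes = ",
      sum(x$dangling), "\n", sep = "")
  invisible(x)
}

# Nodes reachable from `seeds` in the symmetrized graph (W > 0 edges).
# Used to identify the stable-white set: nodes with no path to any pinned
# node keep spin 0 in every realization.
reachable_set <- function(W, seeds) {
  N <- nrow(W)
  seen <- logical(N)
  seen[seeds] <- TRUE
  frontier <- seeds
  Wt <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  while (length(frontier) > 0L) {
    nbr <- unique(unlist(lapply(frontier, function(j) {
      Wt@i[seq.int(Wt@p[j] + 1L, length.out = Wt@p[j + 1L] - Wt@p[j])] + 1L
    }), use.names = FALSE))
    frontier <- nbr[!seen[nbr]]
    seen[frontier] <- TRUE
  }
  which(seen)
}
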