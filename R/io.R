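#' Read a semicolon-delimited coordinate (GM) file
#'
#' One line per specimen: a name field followed by the centroid coordinates
#' stored sequentially (x, y[, z] per point); a trailing delimiter is
#' tolerated. All specimens must have the same number of coordinates, and
#' that number must be divisible by `dims`.
#'
#' @param path file path.
#' @param dims coordinate dimensions per point (2 or 3 typically).
#' @return list of class `"gm_dataset"`: `ids` (specimen names), `coords`
#'   (specimen x (points*dims) numeric matrix, columns ordered
#'   point-within-dimension, ready for [tccn()]), `dims`, `n_points`.
#' @export
read_gm <- function(path, dims = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ";", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  vals <- lapply(parts, function(p) {
    p <- trimws(p[-1L])
    as.numeric(p[nzchar(p)])
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L)
    stop("ragged GM file: line ", which(lens != lens[1])[1],
         " has ", lens[which(lens != lens[1])[1]], " coordinates, expected ",
         lens[1])
  if (any(vapply(vals, anyNA, TRUE)))
    stop("non-numeric coordinate in GM file")
  if (lens[1] %% dims != 0L)
    stop("coordinate count ", lens[1], " not divisible by dims = ", dims)
  n_points <- lens[1] %/% dims
  # file stores x1 y1 z1 x2 y2 z2 ...; regroup to all-x, all-y, all-z
  seqmat <- do.call(rbind, vals)
  idx <- as.vector(outer(seq_len(n_points), seq_len(dims),
                         function(pt, k) (pt - 1L) * dims + k))
  coords <- seqmat[, idx, drop = FALSE]
  rownames(coords) <- ids
  colnames(coords) <- rep(paste0("p", seq_len(n_points)), dims)
  structure(list(ids = ids, coords = coords, dims = dims,
                 n_points = n_points),
            class = "gm_dataset")
}

#' Write a GM coordinate file
#'
#' Inverse of [read_gm()]: writes one semicolon-delimited line per specimen
#' with the name first and coordinates stored sequentially (x, y[, z] per
#' point), with a trailing delimiter.
#'
#' @param gm a `gm_dataset`, or a matrix with specimen ids as rownames
#'   (columns ordered point-within-dimension).
#' @param path output path.
#' @param dims dimensions (taken from a `gm_dataset` automatically).
#' @export
write_gm <- function(gm, path, dims = 3L) {
  if (inherits(gm, "gm_dataset")) {
    coords <- gm$coords; ids <- gm$ids; dims <- gm$dims
  } else {
    coords <- as.matrix(gm)
    ids <- rownames(coords)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(coords)))
  }
  n_points <- ncol(coords) %/% dims
  idx <- as.vector(t(matrix(seq_len(ncol(coords)), n_points, dims)))
  lines <- vapply(seq_len(nrow(coords)), function(i)
    paste0(ids[i], ";", paste(coords[i, idx], collapse = ";"), ";"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a Senate roll-call vote table
#'
#' Space-delimited dialect: each line is one senator — senator code, state
#' (2-letter), party number, last name, then the roll-call vote codes. Vote
#' codes are mapped to numeric +1 (yea), -1 (nay) or NA (absent/abstain) via
#' `vote_map`; pairs with missing votes are handled pairwise-complete
#' downstream.
#'
#' @param path file path.
#' @param vote_map named numeric vector mapping code characters to values.
#'   Default: the common convention, codes 1-3 are forms of yea, 4-6 forms
#'   of nay, everything else missing.
#' @return list of class `"rollcall_table"`: `senators` (data frame with
#'   code, state, party, name), `votes` (senator x motion numeric matrix,
#'   rownames "name_state").
#' @export
read_rollcall <- function(path,
                          vote_map = c("1" = 1, "2" = 1, "3" = 1,
                                       "4" = -1, "5" = -1, "6" = -1)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(parts) < 5L)
  if (length(bad))
    stop("malformed roll-call row ", bad[1], ": fewer than 5 fields")
  sen <- data.frame(
    code = vapply(parts, `[`, "", 1L),
    state = vapply(parts, `[`, "", 2L),
    party = vapply(parts, `[`, "", 3L),
    name = vapply(parts, `[`, "", 4L),
    stringsAsFactors = FALSE)
  codes <- lapply(parts, function(p) {
    v <- p[-(1:4)]
    if (length(v) == 1L && nchar(v) > 1L) v <- strsplit(v, "")[[1]]
    v
  })
  lens <- lengths(codes)
  width <- max(lens)
  votes <- t(vapply(codes, function(v) {
    out <- unname(vote_map[v])
    length(out) <- width  # pad short vote strings with NA
    out
  }, numeric(width)))
  rownames(votes) <- make.unique(paste(sen$name, sen$state, sep = "_"))
  structure(list(senators = sen, votes = votes),
            class = "rollcall_table")
}

#' Read an adjacency/contact edge list
#'
#' Tab-separated file of label pairs, one edge per line (listed once
#' suffices; the matrix is symmetrized). A label paired with itself declares
#' an isolated node: it enters the node set but the diagonal stays false
#' (the bundled US state adjacency uses this for Alaska and Hawaii). Labels
#' not present in `nodes` trigger a warning and are ignored. An empty file
#' yields an all-false matrix. Header lines ("from"/"to" style) are skipped.
#'
#' @param path file path.
#' @param nodes character vector of node labels defining the matrix order;
#'   if `NULL`, the union of labels in the file (sorted) is used.
#' @return symmetric logical matrix with zero diagonal.
#' @export
read_adjacency <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    if (is.null(nodes)) stop("empty adjacency file and no node list")
    m <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    return(m)
  }
  parts <- strsplit(trimws(lines), "\t", fixed = TRUE)
  short <- which(lengths(parts) < 2L)
  if (length(short)) stop("adjacency line ", short[1], " has no pair")
  from <- vapply(parts, `[`, "", 1L)
  to <- vapply(parts, `[`, "", 2L)
  if (tolower(from[1]) %in% c("from", "source", "a") &&
      tolower(to[1]) %in% c("to", "target", "b")) {
    from <- from[-1L]; to <- to[-1L]
  }
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  m <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  unknown <- setdiff(unique(c(from, to)), nodes)
  if (length(unknown)) {
    warning("ignoring labels absent from the node set: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ..." else "")
    keep <- from %in% nodes & to %in% nodes
    from <- from[keep]; to <- to[keep]
  }
  m[cbind(from, to)] <- TRUE
  m[cbind(to, from)] <- TRUE
  diag(m) <- FALSE
  m
}

#' Expand a state adjacency into a senator contact matrix
#'
#' Two senators are in contact when their states are adjacent or identical
#' (same-state colleagues count as distance-0 neighbours; excluding them
#' would disconnect every state's own delegation).
#'
#' @param states character vector: the state of each senator.
#' @param state_adjacency symmetric logical matrix over state labels, e.g.
#'   from [read_adjacency()] on the bundled `us_state_adjacency.tsv`.
#' @return symmetric logical senator x senator matrix, zero diagonal.
#' @export
senator_contacts <- function(states, state_adjacency) {
  missing_states <- setdiff(unique(states), rownames(state_adjacency))
  if (length(missing_states))
    warning("states without adjacency rows (treated as isolated): ",
            paste(missing_states, collapse = ", "))
  p <- length(states)
  m <- matrix(FALSE, p, p)
  known <- states %in% rownames(state_adjacency)
  same <- outer(states, states, `==`)
  adj <- matrix(FALSE, p, p)
  if (any(known)) {
    sub <- state_adjacency[states[known], states[known], drop = FALSE]
    adj[known, known] <- sub
  }
  m <- same | adj
  diag(m) <- FALSE
  m
}

#' Write a weighted edge list
#'
#' Writes the positive-weight edges of a graph as a three-column
#' tab-separated file (`from`, `to`, `weight`), each unordered edge once.
#'
#' @param graph a `corr_graph` or symmetric weight matrix.
#' @param path output path.
#' @export
write_edgelist <- function(graph, path) {
  w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
  labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("v", seq_len(nrow(w)))
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]],
                   weight = w[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a graph's weight matrix as square CSV
#'
#' Full symmetric matrix with node labels as header and first column;
#' readable back with `read.csv(..., row.names = 1)`.
#'
#' @param graph a `corr_graph` or symmetric weight matrix.
#' @param path output path.
#' @export
write_graph_matrix <- function(graph, path) {
  w <- if (inherits(graph, "corr_graph")) graph$weights else as.matrix(graph)
  utils::write.csv(as.data.frame(w), path, row.names = TRUE)
  invisible(path)
}

#' Write a membership vector as TSV
#'
#' @param membership named factor or vector of cluster labels.
#' @param path output path.
#' @export
write_membership <- function(membership, path) {
  nodes <- names(membership)
  if (is.null(nodes)) nodes <- paste0("v", seq_along(membership))
  utils::write.table(
    data.frame(node = nodes, cluster = as.character(membership)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
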