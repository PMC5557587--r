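#' Signed prior-knowledge networks and their AND/OR hypergraph expansion
#'
#' A prior-knowledge network is a signed digraph: edges \code{source ->
#' target} with sign +1 (activation) or -1 (inhibition).  The expansion
#' enumerates, for every target, all singleton hyperedges (one per incoming
#' signed edge) and all AND-gate hyperedges combining 2..\code{max_and_order}
#' distinct regulators; the OR between a node's hyperedges is implicit in the
#' dynamics.
#'
#' @name hypergraph
NULL

#' Construct a signed edge table
#'
#' @param source,target character vectors of species names
#' @param sign vector of +1 / -1 (aliases "activates"/"inhibits", "+"/"-"
#'   accepted)
#' @param allow_self_loops allow edges with source == target
#' @return data.frame with columns source, target, sign
#' @export
signed_edges <- function(source, target, sign, allow_self_loops = FALSE) {
  sign <- .parse_sign(sign)
  source <- as.character(source); target <- as.character(target)
  if (length(source) != length(target) || length(source) != length(sign))
    stop("source, target and sign must have equal length")
  if (!allow_self_loops && any(source == target))
    stop("self-loop edge(s) found: ",
         paste(unique(source[source == target]), collapse = ", "))
  df <- data.frame(source = source, target = target, sign = sign,
                   stringsAsFactors = FALSE)
  dup <- duplicated(df)
  if (any(dup))
    stop("duplicate signed edge(s): ",
         paste(sprintf("%s -> %s (%+d)", df$source[dup], df$target[dup],
                       df$sign[dup]), collapse = ", "))
  df
}

.parse_sign <- function(sign) {
  if (is.character(sign)) {
    map <- c("1" = 1, "-1" = -1, "+" = 1, "-" = -1,
             "activates" = 1, "inhibits" = -1)
    bad <- !(sign %in% names(map))
    if (any(bad)) stop("unknown relation token(s): ",
                       paste(unique(sign[bad]), collapse = ", "))
    sign <- unname(map[sign])
  }
  sign <- as.numeric(sign)
  if (!all(sign %in% c(-1, 1))) stop("edge signs must be +1 or -1")
  sign
}

#' Expand a signed network into an AND/OR hypergraph
#'
#' For each target with incoming signed edges \eqn{d}, generates the
#' \eqn{d} singleton hyperedges plus all AND gates of each order
#' 2..\code{max_and_order} over distinct regulators, giving
#' \eqn{d + \binom{d}{2}} hyperedges at the default order 2.  Hyperedges are
#' ordered deterministically (by target name, then order, then the sorted
#' input set) so selector indices are reproducible across runs and platforms.
#'
#' Species with no incoming edges are the network inputs: they carry no
#' hyperedges and are clamped to their experimental stimulus level during
#' simulation.
#'
#' @param edges a data.frame as returned by \code{\link{signed_edges}}
#' @param max_and_order maximum AND-gate arity (default 2)
#' @param species optional character vector fixing the species universe and
#'   order; defaults to the sorted union of sources and targets
#' @return an object of class \code{hypergraph}: list with \code{species},
#'   \code{hyperedges} (list of \code{list(id, target, inputs)} where
#'   \code{inputs} is a data.frame with columns \code{species}, \code{sign}),
#'   and \code{input_species}
#' @examples
#' net <- signed_edges(c("A", "B"), c("C", "C"), c(1, -1))
#' hg  <- expand_prior_network(net)
#' length(hg$hyperedges)  # 3: (A), (B), (A AND B)
#' @export
expand_prior_network <- function(edges, max_and_order = 2L, species = NULL) {
  if (max_and_order < 1L) stop("max_and_order must be >= 1")
  edges <- signed_edges(edges$source, edges$target, edges$sign)
  if (is.null(species)) {
    species <- sort(unique(c(edges$source, edges$target)))
  } else {
    species <- as.character(species)
    missing <- setdiff(unique(c(edges$source, edges$target)), species)
    if (length(missing))
      stop("edge species not in the species universe: ",
           paste(missing, collapse = ", "))
  }
  hyperedges <- list()
  for (tgt in species) {
    inc <- edges[edges$target == tgt, , drop = FALSE]
    if (nrow(inc) == 0L) next
    # deterministic input order: by species then sign
    inc <- inc[order(inc$source, inc$sign), , drop = FALSE]
    d <- nrow(inc)
    for (ord in seq_len(min(max_and_order, d))) {
      combs <- utils::combn(d, ord)
      # drop AND gates repeating a species (conflicting-sign duplicates give
      # two singletons but no pair)
      keep <- apply(combs, 2L, function(ix) !anyDuplicated(inc$source[ix]))
      combs <- combs[, keep, drop = FALSE]
      if (ncol(combs) == 0L) next
      key <- apply(combs, 2L, function(ix)
        paste(inc$source[ix], inc$sign[ix], collapse = "|"))
      for (j in order(key)) {
        ix <- combs[, j]
        hyperedges[[length(hyperedges) + 1L]] <- list(
          id = NA_integer_, target = tgt,
          inputs = data.frame(species = inc$source[ix], sign = inc$sign[ix],
                              stringsAsFactors = FALSE))
      }
    }
  }
  for (i in seq_along(hyperedges)) hyperedges[[i]]$id <- i
  targets_with_edges <- unique(edges$target)
  structure(list(species = species,
                 hyperedges = hyperedges,
                 input_species = setdiff(species, targets_with_edges)),
            class = "hypergraph")
}

#' @export
print.hypergraph <- function(x, ...) {
  cat("Expanded logic hypergraph\n")
  cat("  species:     ", length(x$species), "  (",
      length(x$input_species), " inputs)\n", sep = "")
  cat("  hyperedges:  ", length(x$hyperedges), "\n", sep = "")
  ord <- vapply(x$hyperedges, function(e) nrow(e$inputs), 1L)
  if (length(ord)) cat("  gate orders: ",
                       paste(names(table(ord)), table(ord), sep = "x",
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

# hyperedges incoming to each species, as a list of integer id vectors
incoming_hyperedges <- function(hg) {
  out <- stats::setNames(vector("list", length(hg$species)), hg$species)
  for (e in hg$hyperedges) out[[e$target]] <- c(out[[e$target]], e$id)
  out
}

#' Read / write SIF network files
#'
#' Whitespace-separated lines \code{source relation target}, relation one of
#' \code{1}, \code{-1} (aliases \code{activates}/\code{inhibits}, \code{+}/
#' \code{-}).  Writing uses \code{1}/\code{-1}; write-then-read round-trips
#' exactly.
#'
#' @param path file path
#' @return \code{read_sif}: a signed-edge data.frame
#' @export
read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  src <- tgt <- character(0); sgn <- numeric(0)
  for (i in which(keep)) {
    tok <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(tok) != 3L)
      stop("SIF line ", i, ": expected 'source relation target', got: ",
           lines[i])
    s <- tryCatch(.parse_sign(tok[2L]),
                  error = function(e) stop("SIF line ", i, ": ",
                                           conditionMessage(e), call. = FALSE))
    src <- c(src, tok[1L]); tgt <- c(tgt, tok[3L]); sgn <- c(sgn, s)
  }
  signed_edges(src, tgt, sgn)
}

#' @rdname read_sif
#' @param edges signed-edge data.frame
#' @export
write_sif <- function(edges, path) {
  writeLines(sprintf("%s %d %s", edges$source, as.integer(edges$sign),
                     edges$target), path)
  invisible(path)
}
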