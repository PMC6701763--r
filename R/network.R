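# Statistical-parsimony (TCS-style) haplotype networks. Haplotypes are joined
# in ascending-distance order through chains of inferred intermediate nodes,
# up to the connection limit: the largest number of mutational steps that can
# be accepted with probability >= alpha of involving no hidden multiple
# substitutions. Loop-breaking heuristics of the original cladogram-estimation
# procedure are reduced to the frequency tie-break; alternative equal-length
# connections are retained as reticulations.

#' Pairwise Hamming distance matrix
#'
#' @param seqs Character vector of equal-length sequences (may be named).
#' @return Symmetric integer matrix of per-pair differing sites.
#' @export
hamming_matrix <- function(seqs) {
  if (length(seqs) == 0) return(matrix(integer(0), 0, 0))
  lens <- nchar(seqs)
  if (any(lens != lens[1])) {
    abort("sequences must have equal length", class = "mothwaves_alignment_error")
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- length(seqs)
  d <- matrix(0L, n, n)
  if (n > 1) {
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
      }
    }
  }
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Probability that j observed differences reflect exactly j mutations
#'
#' The parsimony probability behind the connection limit. Sites mutate
#' independently (Poisson counts, Jukes-Cantor base chain); the per-site rate
#' is set so the expected number of visibly differing sites equals `j`; the
#' returned value is `P(total mutations = j | j sites differ)` — i.e. the
#' probability that no differing site hides a multiple hit and no identical
#' site hides a reversion.
#'
#' @param j Number of observed differences (mutational steps), `j >= 1`.
#' @param length_bp Alignment length in base pairs.
#' @return Probability in `(0, 1)`; decreasing in `j`, increasing in
#'   `length_bp`.
#' @export
parsimony_probability <- function(j, length_bp) {
  stopifnot(j >= 1, length_bp >= 1, j <= length_bp)
  # beyond the Jukes-Cantor saturation ceiling (3/4 of sites visibly
  # different) no mutation rate can make j expected differences: never
  # parsimonious
  if (j >= 0.75 * length_bp) return(0)
  # P(site visibly differs | per-site Poisson(mu) mutations, JC chain):
  # a walk of r steps on the 4-base chain ends off-origin w.p. 3/4(1-(-1/3)^r)
  p_diff <- function(mu) {
    r <- 1:60
    sum(exp(-mu + r * log(mu) - lfactorial(r)) * 0.75 * (1 - (-1 / 3)^r))
  }
  m <- length_bp
  f <- function(mu) m * p_diff(mu) - j
  upper <- 10
  while (f(upper) < 0 && upper < 1e4) upper <- upper * 2
  mu <- uniroot(f, c(1e-14, upper), tol = 1e-13)$root
  pd <- p_diff(mu)
  # parsimony event: each of the j differing sites had exactly 1 mutation,
  # every other site had 0; condition on "j sites differ"
  exp(j * (log(mu) - mu - log(pd)) + (m - j) * (-mu - log1p(-pd)))
}

#' Statistical-parsimony connection limit
#'
#' The largest number of mutational steps `j` whose parsimony probability
#' ([parsimony_probability()]) still reaches `alpha`. Haplotype pairs farther
#' apart than this are left unconnected (separate network components).
#'
#' @param length_bp Alignment length in base pairs.
#' @param alpha Required parsimony probability, default 0.95.
#' @return An object of class `parsimony_limit` with fields
#'   `alignment_length`, `alpha`, `max_steps`.
#' @examples
#' parsimony_limit(590) # 95% limit for a 590-bp COI fragment
#' @export
parsimony_limit <- function(length_bp, alpha = 0.95) {
  if (!is.numeric(length_bp) || length_bp < 1) {
    abort("length_bp must be a positive integer", class = "mothwaves_input_error")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be strictly between 0 and 1", class = "mothwaves_input_error")
  }
  j <- 1
  while (j < length_bp && parsimony_probability(j + 1, length_bp) >= alpha) {
    j <- j + 1
  }
  if (parsimony_probability(1, length_bp) < alpha) j <- 1 # floor: max_steps >= 1
  structure(
    list(alignment_length = as.integer(length_bp), alpha = alpha,
         max_steps = as.integer(j)),
    class = "parsimony_limit"
  )
}

#' @export
print.parsimony_limit <- function(x, ...) {
  cat("<parsimony_limit> ", x$max_steps, " steps at alpha = ", x$alpha,
      " (", x$alignment_length, " bp)\n", sep = "")
  invisible(x)
}

#' Build a statistical-parsimony haplotype network
#'
#' Joins haplotype pairs in ascending Hamming-distance order (ties broken by
#' higher combined total count, then table order), inserting abstract inferred
#' intermediates so that every edge spans exactly one mutational step. A pair
#' is skipped when the network already connects it by a path no longer than
#' its observed distance; equal-length alternatives therefore persist as
#' reticulations. Pairs beyond the connection limit stay in separate
#' components.
#'
#' @param ht A `hap_table` with sequences.
#' @param limit A `parsimony_limit`, or `NULL` to compute one from the
#'   haplotype sequence length and `alpha`.
#' @param alpha Parsimony probability used when `limit` is `NULL`.
#' @return An object of class `parsimony_network`: `nodes` tibble
#'   (`name`, `kind` sampled/inferred, `frequency`), `edges` tibble
#'   (`from`, `to`), `components` tibble (`name`, `component`), and the
#'   `limit` used.
#' @export
build_network <- function(ht, limit = NULL, alpha = 0.95) {
  stopifnot(inherits(ht, "hap_table"))
  require_sequences(ht)
  hap <- ht$haplotypes
  if (is.null(limit)) {
    limit <- parsimony_limit(nchar(hap$sequence[1]), alpha)
  }
  stopifnot(inherits(limit, "parsimony_limit"))
  d <- hamming_matrix(setNames(hap$sequence, hap$name))
  g <- igraph::make_empty_graph(n = nrow(hap), directed = FALSE)
  igraph::V(g)$name <- hap$name
  inferred <- character(0)
  n_inferred <- 0
  if (nrow(hap) > 1) {
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    ord <- order(
      d[pairs],
      -(hap$total_count[pairs[, 1]] + hap$total_count[pairs[, 2]]),
      pairs[, 1], pairs[, 2]
    )
    pairs <- pairs[ord, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      dij <- d[i, j]
      if (dij == 0 || dij > limit$max_steps) next
      cur <- suppressWarnings(
        igraph::distances(g, v = hap$name[i], to = hap$name[j])[1, 1]
      )
      if (is.finite(cur) && cur <= dij) next
      if (dij == 1) {
        g <- igraph::add_edges(g, c(hap$name[i], hap$name[j]))
      } else {
        mids <- paste0("med", n_inferred + seq_len(dij - 1))
        n_inferred <- n_inferred + dij - 1
        inferred <- c(inferred, mids)
        g <- igraph::add_vertices(g, length(mids), name = mids)
        chain <- c(hap$name[i], mids, hap$name[j])
        g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)], chain[-1])))
      }
    }
  }
  nodes <- tibble(
    name = igraph::V(g)$name,
    kind = ifelse(igraph::V(g)$name %in% hap$name, "sampled", "inferred"),
    frequency = dplyr::coalesce(
      hap$total_count[match(igraph::V(g)$name, hap$name)], 0L
    )
  )
  el <- igraph::as_edgelist(g)
  comp <- igraph::components(g)
  structure(
    list(
      nodes = nodes,
      edges = tibble(from = el[, 1], to = el[, 2]),
      components = tibble(name = names(comp$membership),
                          component = unname(comp$membership)),
      limit = limit
    ),
    class = "parsimony_network"
  )
}

network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = as.data.frame(net$nodes))
  g
}

#' @export
print.parsimony_network <- function(x, ...) {
  n_s <- sum(x$nodes$kind == "sampled")
  cat("<parsimony_network> ", n_s, " sampled + ", nrow(x$nodes) - n_s,
      " inferred nodes, ", nrow(x$edges), " edges, ",
      max(x$components$component), " component(s); limit ",
      x$limit$max_steps, " steps\n", sep = "")
  invisible(x)
}

#' @export
tidy.parsimony_network <- function(x, ...) {
  dplyr::left_join(x$nodes, x$components, by = "name")
}

#' @export
glance.parsimony_network <- function(x, ...) {
  tibble(
    n_sampled = sum(x$nodes$kind == "sampled"),
    n_inferred = sum(x$nodes$kind == "inferred"),
    n_edges = nrow(x$edges),
    n_components = max(x$components$component),
    max_steps = x$limit$max_steps,
    alpha = x$limit$alpha
  )
}

#' @export
autoplot.parsimony_network <- function(object, seed = 1, ...) {
  g <- network_igraph(object)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$name)]
  ed$y <- nd$y[match(ed$from, nd$name)]
  ed$xend <- nd$x[match(ed$to, nd$name)]
  ed$yend <- nd$y[match(ed$to, nd$name)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed, ggplot2::aes(x = .data$x, y = .data$y,
                                                  xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd, ggplot2::aes(x = .data$x, y = .data$y,
                                                size = pmax(.data$frequency, 1),
                                                shape = .data$kind,
                                                colour = .data$kind)) +
    ggplot2::geom_text(data = nd[nd$kind == "sampled", ],
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::scale_shape_manual(values = c(sampled = 16, inferred = 15)) +
    ggplot2::labs(size = "frequency", shape = NULL, colour = NULL) +
    ggplot2::theme_void()
}

#' Export a parsimony network
#'
#' `gml` writes a single GML file via igraph (node `kind` and `frequency`
#' preserved as attributes); `tsv` writes `<stem>.nodes.tsv` and
#' `<stem>.edges.tsv`; `dot` writes a Graphviz file.
#'
#' @param net A `parsimony_network`.
#' @param path Output path (for `tsv`, the stem: suffixes are appended).
#' @param format One of `"gml"`, `"tsv"`, `"dot"`.
#' @return The path(s) written, invisibly.
#' @export
export_network <- function(net, path, format = c("gml", "tsv", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "parsimony_network"))
  if (format == "gml") {
    igraph::write_graph(network_igraph(net), path, format = "gml")
    return(invisible(path))
  }
  if (format == "dot") {
    igraph::write_graph(network_igraph(net), path, format = "dot")
    return(invisible(path))
  }
  stem <- sub("\\.tsv$", "", path)
  nodes_path <- paste0(stem, ".nodes.tsv")
  edges_path <- paste0(stem, ".edges.tsv")
  readr::write_tsv(net$nodes, nodes_path)
  readr::write_tsv(net$edges, edges_path)
  invisible(c(nodes_path, edges_path))
}

#' Import a parsimony network written by [export_network()]
#'
#' @param path GML file path, or the TSV stem used at export time.
#' @param format `"gml"` or `"tsv"`.
#' @return A `parsimony_network` (without a connection limit, which is not
#'   serialized; the `limit` field is `NULL`).
#' @export
import_network <- function(path, format = c("gml", "tsv")) {
  format <- match.arg(format)
  if (format == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    nm <- igraph::vertex_attr(g, "name")
    if (is.null(nm)) nm <- igraph::vertex_attr(g, "label")
    nodes <- tibble(
      name = as.character(nm),
      kind = as.character(igraph::vertex_attr(g, "kind")),
      frequency = as.integer(igraph::vertex_attr(g, "frequency"))
    )
    el <- igraph::as_edgelist(g, names = FALSE)
    edges <- tibble(from = nodes$name[el[, 1]], to = nodes$name[el[, 2]])
  } else {
    stem <- sub("\\.tsv$", "", path)
    nodes <- readr::read_tsv(paste0(stem, ".nodes.tsv"), show_col_types = FALSE)
    edges <- readr::read_tsv(paste0(stem, ".edges.tsv"), show_col_types = FALSE)
    nodes$frequency <- as.integer(nodes$frequency)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = as.data.frame(nodes))
  comp <- igraph::components(g)
  structure(
    list(nodes = as_tibble(nodes), edges = as_tibble(edges),
         components = tibble(name = names(comp$membership),
                             component = unname(comp$membership)),
         limit = NULL),
    class = "parsimony_network"
  )
}
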