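#' Build a bipartite question-topic (or question-group) network
#'
#' One left node per question, one right node per topic or semantic group,
#' and an edge wherever the question's profile frequency strictly exceeds
#' `cutoff` (default 1, so an edge means "more than one expected token" of
#' that topic or group). Right nodes are namespaced (`topic:3`,
#' `group:PHYS`) so topic and group networks can later be merged; isolated
#' nodes are dropped.
#'
#' @param profiles list of `QueryTopicProfile` or `SemanticGroupProfile`
#'   objects (one kind per call).
#' @param cutoff edge threshold; edges require frequency > cutoff.
#' @return object of class `BipartiteNetwork`: an `igraph` graph (`graph`)
#'   with vertex attribute `side` in \{question, topic, group\} and edge
#'   attribute `weight`, plus the `cutoff` used.
#' @export
build_bipartite <- function(profiles, cutoff = 1) {
  stopifnot(cutoff >= 0, length(profiles) >= 1)
  edges <- do.call(rbind, lapply(profiles, function(p) {
    if (inherits(p, "QueryTopicProfile")) {
      right <- paste0("topic:", seq_along(p$frequencies))
      side <- "topic"; owner <- p$query_id
    } else if (inherits(p, "SemanticGroupProfile")) {
      right <- paste0("group:", names(p$frequencies))
      side <- "group"; owner <- p$owner_id
    } else stop("profiles must be QueryTopicProfile or SemanticGroupProfile")
    keep <- p$frequencies > cutoff
    if (!any(keep)) return(NULL)
    data.frame(from = owner, to = right[keep],
               weight = unname(p$frequencies[keep]),
               right_side = side, stringsAsFactors = FALSE)
  }))
  new_bipartite(edges, cutoff)
}

new_bipartite <- function(edges, cutoff) {
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
  } else {
    verts <- rbind(data.frame(name = unique(edges$from), side = "question",
                              stringsAsFactors = FALSE),
                   unique(data.frame(name = edges$to, side = edges$right_side,
                                     stringsAsFactors = FALSE)))
    g <- igraph::graph_from_data_frame(edges[c("from", "to", "weight")],
                                       directed = FALSE, vertices = verts)
  }
  structure(list(graph = g, cutoff = cutoff), class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat(sprintf("<BipartiteNetwork: %d nodes, %d edges, cutoff %g>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$cutoff))
  invisible(x)
}

bipartite_edges <- function(network) {
  g <- network$graph
  if (igraph::ecount(g) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      weight = numeric(0), right_side = character(0),
                      stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  side <- igraph::V(g)$side
  names(side) <- igraph::V(g)$name
  # orient each edge question -> right node
  flip <- side[el[, 1]] != "question"
  from <- ifelse(flip, el[, 2], el[, 1])
  to <- ifelse(flip, el[, 1], el[, 2])
  data.frame(from = from, to = to, weight = igraph::E(g)$weight,
             right_side = unname(side[to]), stringsAsFactors = FALSE)
}

#' Merge a topic network and a semantic-group network
#'
#' Union of edges; question nodes shared by the two networks are merged by
#' id, linking the two right-node families through their common questions.
#' Right-node namespaces must be disjoint (guaranteed by the `topic:` /
#' `group:` prefixes; a node id appearing with two different sides is an
#' error).
#'
#' @param a,b `BipartiteNetwork` objects.
#' @return combined `BipartiteNetwork` (cutoff is the pairwise max).
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "BipartiteNetwork"), inherits(b, "BipartiteNetwork"))
  ea <- bipartite_edges(a); eb <- bipartite_edges(b)
  sides <- rbind(unique(ea[c("to", "right_side")]),
                 unique(eb[c("to", "right_side")]))
  clash <- tapply(sides$right_side, sides$to, function(s) length(unique(s)))
  if (any(clash > 1))
    stop("right-node id used with conflicting sides: ",
         paste(names(clash)[clash > 1], collapse = ", "))
  edges <- unique(rbind(ea, eb))
  new_bipartite(edges, max(a$cutoff, b$cutoff))
}

#' Export a bipartite network for external graph tools
#'
#' @param network a `BipartiteNetwork`.
#' @param path output file.
#' @param format `"graphml"` (round-trippable, attributes preserved),
#'   `"sif"` (`question matches right-node` interaction lines), or `"tsv"`
#'   (edge list `from`, `to`, `weight`).
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "sif", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "BipartiteNetwork"))
  edges <- bipartite_edges(network)
  switch(format,
    graphml = igraph::write_graph(network$graph, path, format = "graphml"),
    sif = writeLines(if (nrow(edges)) sprintf("%s matches %s", edges$from, edges$to)
                     else character(0), path),
    tsv = write.table(edges[c("from", "to", "weight")], path, sep = "\t",
                      quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Category-by-topic cosine similarity matrix
#'
#' Reproduces the heat-map analysis comparing question categories with the
#' material corpus's topics. Each category is represented by a centroid over
#' the union vocabulary of the two corpora; each topic by its topic-word
#' distribution mapped onto the same vocabulary. Two category weightings are
#' available:
#' \describe{
#'   \item{tfidf}{summed raw term counts of the category's questions,
#'     weighted by the material index's idf (maximum idf for terms the
#'     materials never use), L2-normalized. With fully disjoint surface
#'     vocabularies every cosine is 0.}
#'   \item{topic_dist}{the category's questions are folded into the topic
#'     model, their mean topic mixture is pushed through phi, giving the
#'     expected word distribution of the category under the model.}
#' }
#' Row and column display orders come from average-linkage hierarchical
#' clustering of Euclidean distances.
#'
#' @param question_corpus a `Corpus` whose documents all carry a category.
#' @param model a fitted `LdaModel` on the materials corpus.
#' @param vsm a `VsmIndex` on the materials corpus (idf source).
#' @param mode `"tfidf"` or `"topic_dist"`.
#' @param fold_in_iter,seed fold-in settings for `mode = "topic_dist"`.
#' @return object of class `SimilarityMatrix`: `values` (categories x
#'   topics), `row_order`, `col_order`, `mode`.
#' @export
category_topic_similarity <- function(question_corpus, model, vsm,
                                      mode = c("tfidf", "topic_dist"),
                                      fold_in_iter = 50L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(question_corpus, "Corpus"), inherits(model, "LdaModel"),
            inherits(vsm, "VsmIndex"))
  cats <- question_corpus$categories
  if (anyNA(cats)) stop("every question must carry a category")
  shared_vocab <- sort(union(question_corpus$vocabulary, model$vocab))
  V <- length(shared_vocab)

  idf <- rep(log(1 + vsm$n_docs) + 1, V)  # df = 0 default
  hit <- match(vsm$vocab, shared_vocab)
  idf[hit] <- unname(vsm$idf)

  phi_map <- matrix(0, model$K, V)
  phi_map[, match(model$vocab, shared_vocab)] <- model$phi

  levels_cat <- unique(cats)
  rows <- lapply(levels_cat, function(cg) {
    members <- which(cats == cg)
    if (mode == "tfidf") {
      counts <- numeric(V)
      idx <- match(unlist(question_corpus$tokens[members]), shared_vocab)
      tab <- tabulate(idx, V)
      v <- tab * idf
    } else {
      thetas <- vapply(members, function(i)
        fold_in(model, question_corpus$tokens[[i]],
                n_iter = fold_in_iter, seed = seed),
        numeric(model$K))
      v <- as.numeric(colMeans(t(thetas)) %*% phi_map)
    }
    v
  })
  keep <- vapply(rows, function(v) sum(v) > 0, TRUE)
  if (any(!keep))
    warning("dropping categories with no usable questions: ",
            paste(levels_cat[!keep], collapse = ", "))
  M <- do.call(rbind, rows[keep])
  rownames(M) <- levels_cat[keep]

  sim <- t(apply(M, 1L, function(r) cosine_rows(phi_map, r)))
  dim(sim) <- c(nrow(M), model$K)
  dimnames(sim) <- list(rownames(M), paste0("topic", seq_len(model$K)))

  row_order <- if (nrow(sim) > 2L)
    stats::hclust(stats::dist(sim), method = "average")$order
  else seq_len(nrow(sim))
  col_order <- if (ncol(sim) > 2L)
    stats::hclust(stats::dist(t(sim)), method = "average")$order
  else seq_len(ncol(sim))
  structure(list(values = sim, row_order = row_order, col_order = col_order,
                 mode = mode),
            class = "SimilarityMatrix")
}

#' Write a similarity matrix with its clustering orders
#'
#' TSV matrix plus a YAML sidecar (`<path>.order.yaml`) recording the
#' dendrogram row/column display orders.
#'
#' @param sim a `SimilarityMatrix`.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sim, path) {
  stopifnot(inherits(sim, "SimilarityMatrix"))
  write.table(sim$values, path, sep = "\t", quote = FALSE, col.names = NA)
  yaml::write_yaml(list(mode = sim$mode,
                        row_order = rownames(sim$values)[sim$row_order],
                        col_order = colnames(sim$values)[sim$col_order]),
                   paste0(path, ".order.yaml"))
  invisible(path)
}
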