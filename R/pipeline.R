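# DAG pipeline engine with JSON serialization.
#
# Operations are small named functions registered in a package-level
# registry; a pipeline is a directed acyclic graph of nodes, each invoking
# one operation with a parameter map. Frame sequences are processed in
# batches; the output never depends on the batch size or on traversal order
# among independent nodes (topological order with ties broken by node id).

the_ops <- new.env(parent = emptyenv())

#' Register a pipeline operation
#'
#' An operation is a function whose first argument is the node input; its
#' remaining (named) formals are the admissible node parameters. Unknown
#' parameters in a pipeline file are rejected, to catch typos.
#'
#' @param name Operation name.
#' @param fn Function `(input, ...named params...)`.
#' @return `name`, invisibly.
#' @export
register_pipeline_op <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = the_ops)
  invisible(name)
}

#' @rdname register_pipeline_op
#' @export
pipeline_ops <- function() sort(ls(the_ops))

register_builtin_ops <- function() {
  register_pipeline_op("identity", function(input) input)
  register_pipeline_op("display_gamma", function(input, exponent = 1) {
    display_gamma(input, exponent)
  })
  register_pipeline_op("slog3_linearize", function(input, apply_scale = TRUE) {
    slog3_to_linear(input, apply_scale = apply_scale)
  })
  register_pipeline_op("trichromat_false_color", function(input) {
    trichromat_false_color(input)
  })
  register_pipeline_op("tetrachromat_false_color",
                       function(input, uv_weight = 0.5) {
    tetrachromat_false_color(input, uv_weight)
  })
  register_pipeline_op("scale", function(input, factor = 1) input * factor)
  register_pipeline_op("combine", function(input) input)
}

#' Mark a list of frames as a batchable sequence
#'
#' Sequences marked this way are streamed through pipeline operations in
#' batches of `batch_size` frames.
#'
#' @param x A list of frames.
#' @return `x` with class `qc_frames`.
#' @export
frames <- function(x) structure(as.list(x), class = "qc_frames")

#' Pipeline graph
#'
#' @param nodes List of `list(id = , op = , params = list())` entries.
#' @param edges List of `c(src_id, dst_id)` pairs.
#' @param version Schema version.
#' @return An object of class `pipeline_graph`, with nodes in a
#'   deterministic topological order.
#' @export
pipeline_graph <- function(nodes, edges = list(), version = 1) {
  ids <- vapply(nodes, function(n) n$id, character(1))
  if (anyDuplicated(ids)) abort("Node ids must be unique.")
  for (n in nodes) {
    if (!n$op %in% pipeline_ops()) {
      abort(sprintf("Unknown operation '%s' in node '%s'.", n$op, n$id))
    }
    fn <- get(n$op, envir = the_ops)
    allowed <- setdiff(names(formals(fn)), names(formals(fn))[1])
    params <- n$params %||% list()
    bad <- setdiff(names(params), allowed)
    if (length(bad)) {
      abort(sprintf(
        "Node '%s' (op '%s') has unknown parameter(s): %s.",
        n$id, n$op, paste(bad, collapse = ", ")
      ))
    }
  }
  for (e in edges) {
    if (!all(e %in% ids)) {
      abort(sprintf("Edge [%s -> %s] references unknown node(s).", e[1], e[2]))
    }
  }
  order <- topo_order(ids, edges)   # errors on cycles
  nodes <- setNames(nodes, ids)[order]
  structure(list(version = version, nodes = nodes, edges = edges),
            class = "pipeline_graph")
}

topo_order <- function(ids, edges) {
  indeg <- setNames(rep(0L, length(ids)), ids)
  adj <- setNames(vector("list", length(ids)), ids)
  for (e in edges) {
    indeg[[e[2]]] <- indeg[[e[2]]] + 1L
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
  }
  out <- character(0)
  ready <- sort(names(indeg)[indeg == 0])
  while (length(ready)) {
    v <- ready[1]; ready <- ready[-1]
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(out) != length(ids)) {
    abort(sprintf("Pipeline contains a cycle involving: %s.",
                  paste(setdiff(ids, out), collapse = " -> ")))
  }
  out
}

#' @export
print.pipeline_graph <- function(x, ...) {
  cat(sprintf("<pipeline_graph> v%s, %d node(s), %d edge(s)\n",
              x$version, length(x$nodes), length(x$edges)))
  for (n in x$nodes) cat(sprintf("  %s: %s\n", n$id, n$op))
  invisible(x)
}

#' Save / load a pipeline as JSON
#'
#' Round-trip `save` then `load` reproduces the graph structurally.
#'
#' @param graph A [pipeline_graph()].
#' @param path File path.
#' @return `load_pipeline()` returns a `pipeline_graph`.
#' @export
save_pipeline <- function(graph, path) {
  stopifnot(inherits(graph, "pipeline_graph"))
  jsonlite::write_json(
    list(
      version = graph$version,
      nodes = lapply(unname(graph$nodes), function(n) {
        list(id = n$id, op = n$op, params = n$params %||% setNames(list(), character(0)))
      }),
      edges = lapply(graph$edges, as.list)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$version)) abort("Pipeline JSON lacks a `version` field.")
  nodes <- lapply(j$nodes, function(n) {
    list(id = n$id, op = n$op, params = lapply(n$params, identity))
  })
  edges <- lapply(j$edges, function(e) c(e[[1]], e[[2]]))
  pipeline_graph(nodes, edges, version = j$version)
}

#' Run a pipeline
#'
#' Executes the graph in topological order. Source nodes read their input
#' from `inputs[[id]]`; a node with one parent receives that parent's output
#' directly, with several parents a named list of outputs. Inputs marked
#' with [frames()] are streamed through each node in batches of
#' `batch_size`.
#'
#' @param graph A [pipeline_graph()].
#' @param inputs Named list: one entry per source node.
#' @param batch_size Frames per processing batch (default 8).
#' @param verbose Log per-node timing.
#' @return Named list of the outputs of the graph's sink nodes.
#' @export
run_pipeline <- function(graph, inputs = list(), batch_size = 8,
                         verbose = FALSE) {
  stopifnot(inherits(graph, "pipeline_graph"))
  ids <- names(graph$nodes)
  parents <- setNames(vector("list", length(ids)), ids)
  children <- setNames(vector("list", length(ids)), ids)
  for (e in graph$edges) {
    parents[[e[2]]] <- c(parents[[e[2]]], e[1])
    children[[e[1]]] <- c(children[[e[1]]], e[2])
  }
  values <- list()
  for (id in ids) {
    node <- graph$nodes[[id]]
    input <- if (!length(parents[[id]])) {
      if (!id %in% names(inputs)) {
        abort(sprintf("No input supplied for source node '%s'.", id))
      }
      inputs[[id]]
    } else if (length(parents[[id]]) == 1) {
      values[[parents[[id]]]]
    } else {
      setNames(lapply(parents[[id]], function(p) values[[p]]), parents[[id]])
    }
    fn <- get(node$op, envir = the_ops)
    params <- node$params %||% list()
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(
      {
        if (inherits(input, "qc_frames")) {
          res <- vector("list", length(input))
          starts <- seq(1, length(input), by = batch_size)
          for (s in starts) {
            idx <- s:min(s + batch_size - 1, length(input))
            res[idx] <- lapply(input[idx], function(fr) {
              do.call(fn, c(list(fr), params))
            })
          }
          frames(res)
        } else {
          do.call(fn, c(list(input), params))
        }
      },
      error = function(e) {
        abort(sprintf(
          "Pipeline node '%s' (op '%s', after [%s]) failed: %s",
          id, node$op, paste(parents[[id]], collapse = ", "),
          conditionMessage(e)
        ))
      }
    )
    if (verbose) {
      message(sprintf("node %s (%s): %.3fs", id, node$op,
                      proc.time()[["elapsed"]] - t0))
    }
    values[[id]] <- out
  }
  sinks <- ids[!vapply(children[ids], length, integer(1)) > 0]
  values[sinks]
}
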