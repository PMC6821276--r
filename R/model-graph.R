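#' Construct a model graph
#'
#' @param name model name
#' @param nodes data.frame with columns \code{id}, \code{kind}
#'   ("observed"/"latent") and optionally \code{variable} (cohort variable
#'   the node resolves to; defaults to the node id), or a character vector
#'   of observed node ids.
#' @param edges data.frame with columns \code{src}, \code{dst}, \code{type}
#'   ("regression"/"loading"/"covariance") and optionally \code{fixed}.
#' @param derived list of derived-variable rules applied to a cohort before
#'   fitting (see \code{\link{applyDerived}}).
#' @return a \linkS4class{ModelGraph}
#' @export
modelGraph <- function(name = "model", nodes, edges = NULL, derived = list()) {
  if (is.character(nodes))
    nodes <- data.frame(id = nodes, kind = "observed")
  if (is.null(nodes$kind)) nodes$kind <- "observed"
  if (is.null(nodes$variable)) nodes$variable <- nodes$id
  nodes$variable <- ifelse(is.na(nodes$variable), nodes$id, nodes$variable)
  nodes$variable[nodes$kind == "latent"] <- NA_character_
  if (is.null(edges))
    edges <- data.frame(src = character(), dst = character(),
                        type = character(), fixed = numeric())
  if (is.null(edges$fixed)) edges$fixed <- NA_real_
  edges <- edges[, c("src", "dst", "type", "fixed")]
  g <- new("ModelGraph", name = name,
           nodes = nodes[, c("id", "kind", "variable")],
           edges = edges, derived = derived)
  validObject(g)
  g
}

#' @describeIn modelGraph node table accessor
#' @param graph a \code{ModelGraph}
#' @export
graphNodes <- function(graph) graph@nodes

#' @describeIn modelGraph edge table accessor
#' @export
graphEdges <- function(graph) graph@edges

setMethod("show", "ModelGraph", function(object) {
  cat(sprintf("ModelGraph '%s': %d nodes (%d latent), %d edges\n",
              object@name, nrow(object@nodes),
              sum(object@nodes$kind == "latent"), nrow(object@edges)))
  if (nrow(object@edges)) cat(toModelText(object))
})

#' Build a model graph from its JSON specification
#'
#' The schema has three sections: \code{nodes} (objects with \code{id},
#' optional \code{kind} and \code{variable}), \code{edges} (objects with
#' \code{src}, \code{dst}, \code{type}, optional \code{fixed}) and an
#' optional \code{derived} array of variable-creation rules (\code{op}
#' "group" or "binarize" with the arguments of \code{\link{groupVariables}}
#' / \code{\link{binarize}}), which are materialized in the cohort by
#' \code{\link{applyDerived}} before fitting.
#'
#' @param json path to a JSON file, or a JSON string
#' @return a \linkS4class{ModelGraph}
#' @export
buildGraph <- function(json) {
  spec <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE,
                             simplifyVector = TRUE)
  nodes <- as.data.frame(spec$nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$kind)) nodes$kind <- "observed"
  nodes$kind[is.na(nodes$kind)] <- "observed"
  edges <- if (!is.null(spec$edges))
    as.data.frame(spec$edges, stringsAsFactors = FALSE) else NULL
  derived <- list()
  if (!is.null(spec$derived)) {
    derived <- if (is.data.frame(spec$derived))
      lapply(seq_len(nrow(spec$derived)),
             function(i) as.list(spec$derived[i, , drop = FALSE])) else
      spec$derived
    derived <- lapply(derived, function(d) lapply(d, function(v)
      if (is.list(v) && length(v) == 1L) v[[1]] else v))
  }
  modelGraph(name = spec$name %||% "model", nodes = nodes, edges = edges,
             derived = derived)
}

#' Serialize a model graph to JSON
#'
#' \code{buildGraph(graphToJSON(g))} reproduces the node and edge sets
#' exactly.
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param path optional output file
#' @return the JSON string, invisibly if written to a file
#' @export
graphToJSON <- function(graph, path = NULL) {
  obj <- list(name = graph@name, nodes = graph@nodes, edges = graph@edges)
  if (length(graph@derived)) obj$derived <- graph@derived
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, dataframe = "rows",
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Materialize a graph's derived-variable rules in a cohort
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param x a \linkS4class{Cohort}
#' @return the cohort with every derived variable appended (rules whose
#'   target already exists are skipped, so the call is idempotent)
#' @export
applyDerived <- function(graph, x) {
  for (d in graph@derived) {
    if (d$new_id %in% variableIds(x)) next
    x <- switch(d$op,
      group = groupVariables(x, memberIds = unlist(d$members),
                             newId = d$new_id, mode = d$mode %||% "any",
                             labels = unlist(d$labels) %||% c("WT", "Mutant")),
      binarize = binarize(x, id = d$variable, newId = d$new_id,
                          cutoff = d$cutoff %||% NULL,
                          op = d$comparison %||% ">",
                          map = if (!is.null(d$map)) unlist(d$map) else NULL,
                          labels = unlist(d$labels) %||% NULL),
      stop(sprintf("unknown derived op '%s'", d$op)))
  }
  x
}

.nodeKind <- function(graph) structure(graph@nodes$kind, names = graph@nodes$id)

.survivalNodes <- function(graph, x) {
  obs <- graph@nodes[graph@nodes$kind == "observed", , drop = FALSE]
  sv <- survivalIds(x)
  obs$id[obs$variable %in% sv]
}

#' Validate a model graph against a cohort
#'
#' Produces a side-effect-free report: unresolved observed nodes, the
#' recursive/nonrecursive (cyclic) status of the regression structure
#' (cycles are allowed but require a stability check at the estimates), and
#' unsupported edges leaving a survival node (survival endpoints may only
#' be sinks).
#'
#' @param graph a \linkS4class{ModelGraph}
#' @param x optional \linkS4class{Cohort} to resolve observed nodes in
#' @return list(\code{ok}, \code{structure} ("recursive"/"nonrecursive"),
#'   \code{cycles}, \code{unresolved}, \code{unsupportedEdges},
#'   \code{findings})
#' @export
validateGraph <- function(graph, x = NULL) {
  nd <- graph@nodes; ed <- graph@edges
  findings <- character()
  unresolved <- character()
  survNodes <- character()
  if (!is.null(x)) {
    obs <- nd[nd$kind == "observed", , drop = FALSE]
    unresolved <- obs$id[!obs$variable %in% variableIds(x)]
    if (length(unresolved))
      findings <- c(findings, sprintf(
        "observed node(s) not found in cohort '%s': %s", cohortName(x),
        paste(unresolved, collapse = ", ")))
    survNodes <- .survivalNodes(graph, x)
    bad <- ed[ed$src %in% survNodes & ed$type == "regression", , drop = FALSE]
    if (nrow(bad))
      findings <- c(findings, sprintf(
        "unsupported edge(s) out of a survival node: %s",
        paste(sprintf("%s->%s", bad$src, bad$dst), collapse = ", ")))
    unsupported <- if (nrow(bad)) sprintf("%s->%s", bad$src, bad$dst) else
      character()
  } else unsupported <- character()
  # cycle detection on the regression structure by iterative leaf stripping
  reg <- ed[ed$type == "regression", , drop = FALSE]
  ids <- nd$id
  adj <- reg
  repeat {
    sinksOnly <- setdiff(ids, adj$src)
    drop <- intersect(ids, sinksOnly)
    keep <- adj$dst %in% setdiff(ids, drop)
    ids2 <- setdiff(ids, drop)
    adj2 <- adj[adj$src %in% ids2 & adj$dst %in% ids2, , drop = FALSE]
    if (length(ids2) == length(ids)) break
    ids <- ids2; adj <- adj2
  }
  cyclic <- nrow(adj) > 0
  if (cyclic)
    findings <- c(findings, paste(
      "nonrecursive model (cycle detected): estimation requires the path",
      "matrix to be stable (spectral radius < 1), reported at the fit"))
  list(ok = !length(unresolved) && !length(unsupported),
       structure = if (cyclic) "nonrecursive" else "recursive",
       cycles = cyclic, unresolved = unresolved,
       unsupportedEdges = unsupported, findings = findings)
}

#' Canonical text form of a model graph
#'
#' One line per response ("Y ~ X1 + X2"), per latent definition
#' ("F =~ I1 + I2 + I3") and per covariance ("A ~~ B"), in the canonical
#' node order (insertion order of the node table), so the export is
#' deterministic and round-trippable via \code{\link{graphFromModelText}}.
#'
#' @param graph a \linkS4class{ModelGraph}
#' @return a single string
#' @export
toModelText <- function(graph) {
  nd <- graph@nodes; ed <- graph@edges
  ord <- structure(seq_len(nrow(nd)), names = nd$id)
  lines <- character()
  for (lat in nd$id[nd$kind == "latent"]) {
    ind <- ed$dst[ed$type == "loading" & ed$src == lat]
    if (length(ind))
      lines <- c(lines, sprintf("%s =~ %s", lat,
                                paste(ind[order(ord[ind])], collapse = " + ")))
  }
  reg <- ed[ed$type == "regression", , drop = FALSE]
  for (dst in nd$id[nd$id %in% reg$dst]) {
    src <- reg$src[reg$dst == dst]
    lines <- c(lines, sprintf("%s ~ %s", dst,
                              paste(src[order(ord[src])], collapse = " + ")))
  }
  cv <- ed[ed$type == "covariance", , drop = FALSE]
  if (nrow(cv)) {
    a <- ifelse(ord[cv$src] <= ord[cv$dst], cv$src, cv$dst)
    b <- ifelse(ord[cv$src] <= ord[cv$dst], cv$dst, cv$src)
    o <- order(ord[a], ord[b])
    lines <- c(lines, sprintf("%s ~~ %s", a[o], b[o]))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse the canonical model text back into a graph
#'
#' Understands the three operator families of \code{\link{toModelText}}:
#' \code{~} (regression), \code{=~} (latent definition), \code{~~}
#' (covariance).
#'
#' @param text model text
#' @param name model name
#' @return a \linkS4class{ModelGraph}
#' @export
graphFromModelText <- function(text, name = "model") {
  lines <- trimws(strsplit(text, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nodes <- character(); latents <- character()
  edges <- list()
  addNode <- function(id) if (!id %in% nodes) nodes <<- c(nodes, id)
  for (ln in lines) {
    if (grepl("=~", ln, fixed = TRUE)) {
      pp <- trimws(strsplit(ln, "=~", fixed = TRUE)[[1]])
      lat <- pp[1]; addNode(lat); latents <- union(latents, lat)
      for (ind in trimws(strsplit(pp[2], "+", fixed = TRUE)[[1]])) {
        addNode(ind)
        edges[[length(edges) + 1L]] <- list(lat, ind, "loading")
      }
    } else if (grepl("~~", ln, fixed = TRUE)) {
      pp <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      addNode(pp[1]); addNode(pp[2])
      edges[[length(edges) + 1L]] <- list(pp[1], pp[2], "covariance")
    } else if (grepl("~", ln, fixed = TRUE)) {
      pp <- trimws(strsplit(ln, "~", fixed = TRUE)[[1]])
      dst <- pp[1]; addNode(dst)
      for (src in trimws(strsplit(pp[2], "+", fixed = TRUE)[[1]])) {
        addNode(src)
        edges[[length(edges) + 1L]] <- list(src, dst, "regression")
      }
    } else stop(sprintf("cannot parse model line: '%s'", ln))
  }
  ed <- data.frame(src = vapply(edges, `[[`, "", 1),
                   dst = vapply(edges, `[[`, "", 2),
                   type = vapply(edges, `[[`, "", 3))
  modelGraph(name = name,
             nodes = data.frame(id = nodes,
                                kind = ifelse(nodes %in% latents,
                                              "latent", "observed")),
             edges = ed)
}
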