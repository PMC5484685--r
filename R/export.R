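## build an igraph of a fitted web: nodes are observed variables (with
## group/level attributes when a trophic structure is supplied), directed
## edges are paths, undirected-flagged edges are covariances
websem_graph <- function(fit, structure = NULL) {
  model <- fit$model
  std <- standardize_solution(fit)
  std_of <- stats::setNames(std$standardized, std$parameter)
  p_of <- if (is.null(fit$pvalue))
    stats::setNames(rep(NA_real_, length(fit$theta)), names(fit$theta))
  else fit$pvalue
  edges <- NULL
  if (nrow(model$paths)) {
    lab <- paste0(model$paths$source, "->", model$paths$target)
    edges <- data.frame(from = model$paths$source, to = model$paths$target,
                        relation = "path", estimate = unname(fit$theta[lab]),
                        std_estimate = unname(std_of[lab]),
                        p_value = unname(p_of[lab]),
                        stringsAsFactors = FALSE)
  }
  if (nrow(model$covariances)) {
    lab <- paste0(model$covariances$a, "<~>", model$covariances$b)
    edges <- rbind(edges,
                   data.frame(from = model$covariances$a, to = model$covariances$b,
                              relation = "covariance",
                              estimate = unname(fit$theta[lab]),
                              std_estimate = unname(std_of[lab]),
                              p_value = unname(p_of[lab]),
                              stringsAsFactors = FALSE))
  }
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        relation = character(0), estimate = numeric(0),
                        std_estimate = numeric(0), p_value = numeric(0))
  edges$stars <- p_stars(edges$p_value)
  verts <- data.frame(name = model$variables, stringsAsFactors = FALSE)
  if (!is.null(structure)) {
    grp <- var_group(model$variables, structure)
    verts$group <- grp
    verts$trophic_level <- ifelse(grp == "env", 0L, structure$levels[grp])
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export a fitted web as a graph or parameter table
#'
#' Writes the fitted model as GraphML or DOT (nodes are variables, edges
#' carry the raw and standardised coefficients and significance stars:
#' `***` for P <= 0.001, `**` for P <= 0.01, `*` for P <= 0.05, `ns`
#' otherwise), or as a TSV parameter table with one row per free parameter.
#'
#' @param fit a fitted [websem].
#' @param path output file.
#' @param format `"graphml"`, `"dot"` or `"tsv"`.
#' @param structure optional [trophic_structure] to attach group and level
#'   node attributes.
#' @return `path`, invisibly.
#' @export
export_web <- function(fit, path, format = c("graphml", "dot", "tsv"),
                       structure = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- summary(fit)$parameters
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- websem_graph(fit, structure)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
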