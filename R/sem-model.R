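#' Specify a path model over observed variables
#'
#' A web model is a covariance-structure model in which every variable is
#' observed: directed paths are free regression coefficients, covariances
#' are free (residual) covariances, and every variable carries a free
#' residual variance. Internally the model is held in reticular-action
#' form, with implied covariance
#' `Sigma = (I - B)^-1 Psi (I - B)^-T`, where `B` collects the path
#' coefficients and `Psi` the residual variances and covariances.
#'
#' @param variables character vector of observed-variable names, e.g. two
#'   PCA axes per trophic group (`"herbs.PC1"`) plus `"env.PC1"`,
#'   `"env.PC2"`.
#' @param paths two-column matrix or data frame (`source`, `target`) of
#'   directed paths. The directed graph must be acyclic with no self loops.
#' @param covariances two-column matrix or data frame of free covariance
#'   pairs. A covariance may not connect two variables already joined by a
#'   directed path.
#' @return Object of class `websem_model`.
#' @seealso [websem()] for fitting, [parse_websem_model()] for the
#'   plain-text grammar.
#' @export
websem_model <- function(variables, paths = NULL, covariances = NULL) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) stopf("duplicate variable names")
  norm_pairs <- function(x, what) {
    if (is.null(x) || NROW(x) == 0)
      return(data.frame(source = character(0), target = character(0),
                        stringsAsFactors = FALSE))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    names(x)[1:2] <- c("source", "target")
    x$source <- as.character(x$source); x$target <- as.character(x$target)
    unknown <- setdiff(c(x$source, x$target), variables)
    if (length(unknown))
      stopf("%s refer to undeclared variable(s): %s", what,
            paste(unique(unknown), collapse = ", "))
    if (any(x$source == x$target)) stopf("%s may not be self loops", what)
    x[, c("source", "target")]
  }
  paths <- norm_pairs(paths, "paths")
  if (anyDuplicated(paths)) stopf("duplicate paths")
  covariances <- norm_pairs(covariances, "covariances")
  ## canonicalise covariance pairs (unordered)
  if (nrow(covariances)) {
    sw <- covariances$source > covariances$target
    tmp <- covariances$source[sw]
    covariances$source[sw] <- covariances$target[sw]
    covariances$target[sw] <- tmp
    if (anyDuplicated(covariances)) stopf("duplicate covariances")
  }
  names(covariances) <- c("a", "b")
  ## acyclicity of the directed part
  if (nrow(paths)) {
    g <- igraph::graph_from_data_frame(paths, directed = TRUE,
                                       vertices = variables)
    if (!igraph::is_acyclic(g)) stopf("directed paths contain a cycle")
  }
  ## covariance may not shadow a directed path
  if (nrow(covariances) && nrow(paths)) {
    pk <- c(paste(paths$source, paths$target), paste(paths$target, paths$source))
    ck <- paste(covariances$a, covariances$b)
    bad <- ck %in% pk | paste(covariances$b, covariances$a) %in% pk
    if (any(bad))
      stopf("covariance between variables already joined by a path: %s",
            paste(ck[bad], collapse = "; "))
  }
  structure(list(variables = variables, paths = paths,
                 covariances = covariances),
            class = "websem_model")
}

#' @export
print.websem_model <- function(x, ...) {
  cat(sprintf("websem model: %d variables, %d paths, %d covariances (df = %d)\n",
              length(x$variables), nrow(x$paths), nrow(x$covariances),
              websem_df(x)))
  invisible(x)
}

## number of free parameters and model df
websem_k <- function(model)
  nrow(model$paths) + nrow(model$covariances) + length(model$variables)

websem_df <- function(model) {
  p <- length(model$variables)
  p * (p + 1) / 2 - websem_k(model)
}

#' Parse and write the plain-text model grammar
#'
#' One statement per line: `target <- source` declares a directed path,
#' `a <~> b` a free covariance, and `x ~~ x` (optional, implied) a free
#' residual variance. Blank lines and `#` comments are ignored. Variables
#' are collected from the statements unless supplied.
#'
#' @param lines character vector of statements (or a file read with
#'   `readLines()`).
#' @param variables optional explicit variable set (needed for variables
#'   with no statements).
#' @return A [websem_model].
#' @export
parse_websem_model <- function(lines, variables = NULL) {
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  paths <- covs <- list()
  seen <- character(0)
  for (ln in lines) {
    if (grepl("<~>", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "<~>", fixed = TRUE)[[1]])
      covs[[length(covs) + 1L]] <- pr
      seen <- c(seen, pr)
    } else if (grepl("<-", ln, fixed = TRUE)) {
      pr <- trimws(strsplit(ln, "<-", fixed = TRUE)[[1]])  # target <- source
      paths[[length(paths) + 1L]] <- c(pr[2], pr[1])
      seen <- c(seen, pr)
    } else if (grepl("~~", ln, fixed = TRUE)) {
      seen <- c(seen, trimws(strsplit(ln, "~~", fixed = TRUE)[[1]]))
    } else stopf("cannot parse model statement: '%s'", ln)
  }
  if (is.null(variables)) variables <- unique(seen)
  websem_model(variables,
               paths = if (length(paths)) do.call(rbind, paths),
               covariances = if (length(covs)) do.call(rbind, covs))
}

#' @rdname parse_websem_model
#' @param model a [websem_model].
#' @export
format_websem_model <- function(model) {
  c(if (nrow(model$paths))
      paste(model$paths$target, "<-", model$paths$source),
    if (nrow(model$covariances))
      paste(model$covariances$a, "<~>", model$covariances$b))
}

## parameter labels used throughout (coef names, start values, MI tables)
websem_param_names <- function(model) {
  c(if (nrow(model$paths)) paste0(model$paths$source, "->", model$paths$target),
    paste0("var(", model$variables, ")"),
    if (nrow(model$covariances)) paste0(model$covariances$a, "<~>", model$covariances$b))
}
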