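#' Construct a community matrix
#'
#' A community matrix is a plot-by-species abundance table for one trophic
#' group, carrying the group metadata used downstream (trophic level,
#' above/belowground compartment, producer flag). Plots are rows, species
#' are columns; plot identifiers are character strings.
#'
#' @param abundances numeric matrix, plots in rows, species in columns, with
#'   row and column names. Values must be finite and non-negative.
#' @param group_id character scalar naming the trophic group.
#' @param trophic_level integer trophic rank (1 = producers).
#' @param compartment `"above"` or `"below"`.
#' @param producer logical; is this group a primary producer?
#' @return An object of class `community_matrix`: the abundance matrix with
#'   metadata attributes. Plots whose row sums are zero are flagged in the
#'   `empty_plots` attribute (they are invalid for relative-abundance
#'   ordination but tolerated at construction).
#' @export
community_matrix <- function(abundances, group_id,
                             trophic_level = NA_integer_,
                             compartment = c("below", "above"),
                             producer = FALSE) {
  compartment <- match.arg(compartment)
  abundances <- as.matrix(abundances)
  if (is.null(rownames(abundances)) || is.null(colnames(abundances)))
    stopf("community matrix needs plot (row) and species (column) names")
  if (anyDuplicated(rownames(abundances)))
    stopf("duplicate plot identifiers: %s",
          paste(unique(rownames(abundances)[duplicated(rownames(abundances))]),
                collapse = ", "))
  if (anyDuplicated(colnames(abundances)))
    stopf("duplicate species identifiers: %s",
          paste(unique(colnames(abundances)[duplicated(colnames(abundances))]),
                collapse = ", "))
  if (!is.numeric(abundances) || any(!is.finite(abundances)))
    stopf("group '%s': abundances must be finite numbers", group_id)
  bad <- which(abundances < 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("group '%s': negative abundance at plot '%s', species '%s'",
          group_id, rownames(abundances)[bad[1, 1]],
          colnames(abundances)[bad[1, 2]])
  empty <- rownames(abundances)[rowSums(abundances) == 0]
  structure(abundances,
            group_id = as.character(group_id),
            trophic_level = as.integer(trophic_level),
            compartment = compartment,
            producer = isTRUE(producer),
            empty_plots = empty,
            class = c("community_matrix", "matrix", "array"))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community matrix '%s': %d plots x %d species (level %s, %sground)\n",
              attr(x, "group_id"), nrow(x), ncol(x),
              attr(x, "trophic_level"), attr(x, "compartment")))
  if (length(attr(x, "empty_plots")))
    cat("  empty plots:", paste(attr(x, "empty_plots"), collapse = ", "), "\n")
  invisible(x)
}

#' Read a community abundance table
#'
#' Reads a TSV (or CSV, by file extension) whose first column holds plot
#' identifiers and whose header row holds species identifiers, validates it,
#' and attaches group metadata. Validation errors name the offending row and
#' column.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @inheritParams community_matrix
#' @return A [community_matrix].
#' @export
read_community <- function(path, group_id,
                           trophic_level = NA_integer_,
                           compartment = c("below", "above"),
                           producer = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  if (ncol(raw) < 2) stopf("'%s': expected a plot-id column plus species columns", path)
  plots <- raw[[1]]
  vals <- raw[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad))
    stopf("'%s': non-numeric cell at plot '%s', species '%s'",
          path, plots[bad[1, 1]], colnames(vals)[bad[1, 2]])
  rownames(num) <- plots
  community_matrix(num, group_id = group_id, trophic_level = trophic_level,
                   compartment = compartment, producer = producer)
}

#' Write a community matrix to TSV
#'
#' Inverse of [read_community()]; round-trips are lossless for finite decimal
#' abundances.
#'
#' @param m a [community_matrix] (or plain matrix with dimnames).
#' @param path output file path.
#' @export
write_community <- function(m, path) {
  df <- data.frame(plot = rownames(m), as.data.frame(unclass(m)[, , drop = FALSE],
                                                     check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a plot-by-variable environment table
#'
#' @param path TSV/CSV with first column plot ids and one column per
#'   environmental or spatial variable (the field design used 13).
#' @return A numeric matrix with plot ids as row names, class
#'   `environment_table`. Missing values are a validation error.
#' @export
read_environment <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           comment.char = "")
  plots <- as.character(raw[[1]])
  if (anyDuplicated(plots))
    stopf("'%s': duplicate plot identifiers", path)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    bad <- which(!is.finite(vals) | is.na(vals), arr.ind = TRUE)
    stopf("'%s': missing or non-numeric value at plot '%s', variable '%s'",
          path, plots[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  rownames(vals) <- plots
  structure(vals, class = c("environment_table", "matrix", "array"))
}

#' Align community matrices and an environment table on common plots
#'
#' Restricts every table to the plots present in all of them, in one
#' canonical (sorted) order, so that ordination scores and model data share
#' row identity. Dropped plots are reported with a warning.
#'
#' @param matrices named list of [community_matrix] objects.
#' @param env optional environment matrix (plots in rows).
#' @return A list with elements `matrices`, `env` (or `NULL`) and `plots`
#'   (the common ordered plot ids). Fewer than 5 common plots is an error.
#' @export
align_plots <- function(matrices, env = NULL) {
  sets <- lapply(matrices, rownames)
  if (!is.null(env)) sets <- c(sets, list(rownames(env)))
  common <- Reduce(intersect, sets)
  if (length(common) < 5)
    stopf("only %d plots are common to all tables; need at least 5", length(common))
  common <- sort(common)
  dropped <- setdiff(unique(unlist(sets)), common)
  if (length(dropped))
    warnf("dropping %d plot(s) absent from at least one table: %s",
          length(dropped), paste(dropped, collapse = ", "))
  matrices <- lapply(matrices, function(m) {
    out <- m[common, , drop = FALSE]
    attributes(out) <- c(attributes(out),
                         attributes(m)[c("group_id", "trophic_level",
                                         "compartment", "producer")])
    attr(out, "empty_plots") <- intersect(attr(m, "empty_plots"), common)
    class(out) <- class(m)
    out
  })
  if (!is.null(env)) env <- env[common, , drop = FALSE]
  list(matrices = matrices, env = env, plots = common)
}
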