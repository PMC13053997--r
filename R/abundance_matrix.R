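#' Abundance matrix container
#'
#' Holds a protein-group x sample intensity matrix together with an explicit
#' missingness mask and a processing-state tag. The tag enforces the pipeline
#' order raw -> log2 -> normalized -> batch_corrected -> imputed -> zscored:
#' each preprocessing operation checks that its input is in the expected state
#' and refuses to run out of order.
#'
#' @param values numeric matrix, proteins in rows, samples in columns. Missing
#'   cells are `NA`.
#' @param scale_state processing state tag; one of `"raw"`, `"log2"`,
#'   `"normalized"`, `"batch_corrected"`, `"imputed"`, `"zscored"`.
#' @param mask logical matrix, `TRUE` where a cell was quantified. Defaults to
#'   `!is.na(values)`. After imputation the mask keeps recording which cells
#'   were originally observed even though no `NA` remains.
#'
#' @return An object of class `abundance_matrix` with fields `values`, `mask`,
#'   `scale_state`, `protein_ids`, `sample_ids`.
#' @export
abundance_matrix <- function(values, scale_state = "raw", mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values are not congruent")
  }
  scale_state <- match.arg(scale_state, scale_states())
  structure(
    list(
      values = values,
      mask = mask,
      scale_state = scale_state,
      protein_ids = rownames(values),
      sample_ids = colnames(values)
    ),
    class = "abundance_matrix"
  )
}

scale_states <- function() {
  c("raw", "log2", "normalized", "batch_corrected", "imputed", "zscored")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf(
    "<abundance_matrix> %d proteins x %d samples [%s], %.1f%% quantified\n",
    nrow(x$values), ncol(x$values), x$scale_state, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

# Require that `x` is in one of the admissible states for an operation.
check_state <- function(x, allowed, op) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (!x$scale_state %in% allowed) {
    stop(sprintf(
      "%s expects scale_state in {%s}, got '%s' (pipeline order is %s)",
      op, paste(allowed, collapse = ", "), x$scale_state,
      paste(scale_states(), collapse = " -> ")
    ))
  }
  invisible(TRUE)
}

# Replace values/state, keeping ids and (by default) the mask.
update_matrix <- function(x, values, scale_state, mask = x$mask) {
  dimnames(values) <- dimnames(x$values)
  dimnames(mask) <- dimnames(x$values)
  out <- x
  out$values <- values
  out$mask <- mask
  out$scale_state <- scale_state
  out
}

# Subset proteins by id or index, preserving order.
subset_proteins <- function(x, proteins) {
  v <- x$values[proteins, , drop = FALSE]
  m <- x$mask[proteins, , drop = FALSE]
  out <- abundance_matrix(v, scale_state = x$scale_state, mask = m)
  out
}
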