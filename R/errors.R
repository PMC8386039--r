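#' Classed error conditions
#'
#' All package errors are classed conditions so callers can distinguish
#' failure modes programmatically, e.g.
#' `tryCatch(..., ontozoo_cycle_error = function(e) ...)`.
#'
#' Condition classes in use:
#' \describe{
#'   \item{ontozoo_cycle_error}{cyclic input where a DAG is required}
#'   \item{ontozoo_schema_error}{malformed input: unknown term in an edge,
#'     unknown metadata key, unparseable file}
#'   \item{ontozoo_empty_label_space_error}{no observed terms to build a
#'     label space from}
#'   \item{ontozoo_unknown_term_error}{ontology lookup of a term id that is
#'     not in the DAG}
#'   \item{ontozoo_unmappable_label_error}{a label outside the label-space
#'     subgraph, or an all-zero indicator row}
#'   \item{ontozoo_domain_error}{numeric argument outside its domain
#'     (non-positive mean/dispersion, latent dim too large, degenerate
#'     simulation spec)}
#'   \item{ontozoo_zero_library_error}{cells with zero total count}
#'   \item{ontozoo_missing_feature_error}{gene absent from a dataset's
#'     feature space}
#'   \item{ontozoo_split_scheme_error}{split scheme incompatible with the
#'     card collection}
#'   \item{ontozoo_feature_space_error}{model applied to data in a
#'     different gene space}
#'   \item{ontozoo_training_diverged_error}{non-finite loss during training}
#'   \item{ontozoo_unsupported_model_error}{operation undefined for the
#'     model kind (e.g. gradients of a random projection)}
#'   \item{ontozoo_version_conflict_error}{attempt to overwrite a published
#'     parameter version}
#'   \item{ontozoo_topology_mismatch_error}{published arrays do not match
#'     the declared topology}
#'   \item{ontozoo_integrity_error}{checksum failure on parameter load}
#'   \item{ontozoo_empty_eval_error}{evaluation requested on an empty set}
#' }
#'
#' @param class condition subclass (without the `ontozoo_` prefix)
#' @param msg message, passed through [sprintf()] when `...` is non-empty
#' @param ... sprintf arguments
#' @return no return; always signals
#' @keywords internal
oz_stop <- function(class, msg, ...) {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(paste0("ontozoo_", class), "ontozoo_error")))
}

oz_warn <- function(msg, ...) {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  warning(warningCondition(msg, class = "ontozoo_warning"))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
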