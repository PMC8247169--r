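#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a transition summary into long proportions
#'
#' @param x A `transition_summary` from [transition_contingency()].
#' @param ... Unused.
#' @return Tibble: condition, destination, n, prop.
#' @method tidy transition_summary
#' @export
tidy.transition_summary <- function(x, ...) x$proportions

#' One-row summary of a transition comparison
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return Tibble: source_state, statistic, df, p.
#' @method glance transition_summary
#' @export
glance.transition_summary <- function(x, ...) {
  tibble::tibble(source_state = x$source_state, statistic = x$statistic,
                 df = x$df, p = x$p)
}

#' Tidy an NMF model into long gene loadings
#'
#' @param x An `nmf_model` from [nmf_programs()].
#' @param ... Unused.
#' @return Tibble: gene, factor, loading.
#' @method tidy nmf_model
#' @export
tidy.nmf_model <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$w, responseName = "loading",
                                        stringsAsFactors = FALSE)) |>
    stats::setNames(c("gene", "factor", "loading"))
}

#' One-row summary of an NMF fit
#'
#' @param x An `nmf_model`.
#' @param ... Unused.
#' @return Tibble: sample, n_factors, n_iter, objective (final loss).
#' @method glance nmf_model
#' @export
glance.nmf_model <- function(x, ...) {
  tibble::tibble(sample = x$sample, n_factors = x$n_factors,
                 n_iter = length(x$objective),
                 objective = utils::tail(x$objective, 1))
}

#' Tidy meta-programs into factor membership
#'
#' @param x A `meta_programs` object.
#' @param ... Unused.
#' @return Tibble: sample, factor, meta_program.
#' @method tidy meta_programs
#' @export
tidy.meta_programs <- function(x, ...) x$membership

#' Tidy a CNV matrix into the per-cell aggregate signal
#'
#' @param x A `cnv_matrix` from [infer_cnv()].
#' @param ... Unused.
#' @return Tibble: cell_id, cnv_signal, reference.
#' @method tidy cnv_matrix
#' @export
tidy.cnv_matrix <- function(x, ...) x$aggregate
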