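# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reconciliation summary
#'
#' @param x a `ch_reconciliation`.
#' @param ... unused.
#' @return Tibble with one row per event type (`event`, `n`, `unit_cost`,
#'   `cost`).
#' @export
tidy.ch_reconciliation <- function(x, ...) {
  tibble::tibble(event = c("duplication", "transfer", "loss"),
                 n = c(x$n_dup, x$n_transfer, x$n_loss))
}

#' @rdname tidy.ch_reconciliation
#' @export
glance.ch_reconciliation <- function(x, ...) {
  tibble::tibble(model = x$model, n_dup = x$n_dup, n_transfer = x$n_transfer,
                 n_loss = x$n_loss, total_cost = x$total_cost)
}

#' Tidy an ordination
#'
#' @param x a `ch_ordination`.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... unused.
#' @return Long tibble (`genome_id`/`group_id`, `component`, `value`).
#' @export
tidy.ch_ordination <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  wide <- x[[matrix]]
  id <- names(wide)[1L]
  tidyr::pivot_longer(wide, -dplyr::all_of(id), names_to = "component",
                      values_to = "value")
}

#' @rdname tidy.ch_ordination
#' @export
glance.ch_ordination <- function(x, ...) {
  tibble::tibble(
    n_genomes = nrow(x$scores),
    n_groups = nrow(x$loadings),
    var_pc1 = x$variance_fraction[1L],
    var_pc2 = if (length(x$variance_fraction) > 1L) {
      x$variance_fraction[2L]
    } else NA_real_
  )
}

#' Tidy a transfer screen
#'
#' @param x a `ch_hgt_screen`.
#' @param ... unused.
#' @return The candidate tibble (one row per stage-1 survivor with the
#'   furthest stage it passed and, where tested, the constraint p-value).
#' @export
tidy.ch_hgt_screen <- function(x, ...) x$candidates

#' @rdname tidy.ch_hgt_screen
#' @export
glance.ch_hgt_screen <- function(x, ...) {
  tidyr::pivot_wider(x$report, names_from = "stage", values_from = "n")
}
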