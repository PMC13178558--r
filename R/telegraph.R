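#' Telegraph (two-state promoter) model parameters
#'
#' Rates of the mechanistic ON/OFF promoter model used as an independent
#' oracle for the bursty negative-binomial regime: the promoter switches
#' OFF -> ON at `k_on` and ON -> OFF at `k_off`, transcribes at `k_tx` while
#' ON, and transcripts decay with first-order rate `k_deg`. In the bursty
#' limit (`k_off >> k_on`, `k_tx >> k_off`) the stationary copy-number law
#' approaches NB with burst size `k_tx / k_off` and burst frequency
#' `k_on / k_deg` per mRNA lifetime.
#'
#' @param k_on Promoter activation rate (1/time), >= 0.
#' @param k_off Promoter inactivation rate (1/time), >= 0.
#' @param k_tx Transcription rate in the ON state (1/time), >= 0.
#' @param k_deg mRNA degradation rate (1/time), > 0.
#' @return An object of class `telegraph_params`.
#' @examples
#' telegraph_params(k_on = 0.1, k_off = 10, k_tx = 100, k_deg = 1)
#' @export
telegraph_params <- function(k_on, k_off, k_tx, k_deg) {
  for (nm in c("k_on", "k_off", "k_tx", "k_deg")) {
    check_scalar_num(get(nm), nm)
  }
  if (k_on < 0 || k_off < 0 || k_tx < 0) {
    abort("rates must be >= 0.", class = "burstfish_param_error")
  }
  if (k_deg <= 0) {
    abort("`k_deg` must be > 0.", class = "burstfish_param_error")
  }
  structure(list(k_on = k_on, k_off = k_off, k_tx = k_tx, k_deg = k_deg),
    class = "telegraph_params"
  )
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat(sprintf(
    "<telegraph_params>  k_on = %.4g  k_off = %.4g  k_tx = %.4g  k_deg = %.4g\n",
    x$k_on, x$k_off, x$k_tx, x$k_deg
  ))
  invisible(x)
}

#' Simulate per-cell mRNA counts from the telegraph model
#'
#' Exact stochastic simulation (Gillespie algorithm) of the two-state
#' promoter with transcription and first-order decay; every cell is an
#' independent realization sampled at time `t_end`. Cells start with zero
#' transcripts and a promoter state drawn from the stationary switching law,
#' so `t_end` much longer than `1 / k_deg` guarantees the copy-number
#' distribution has relaxed to steady state.
#'
#' @param params A [telegraph_params] object.
#' @param n_cells Number of independent cells (>= 0).
#' @param t_end Simulated time horizon; must exceed several mRNA lifetimes.
#' @param strain,condition_uM Labels attached to every cell.
#' @param seed Optional integer seed for reproducibility.
#' @return A count dataset tibble (`cell_id`, `strain`, `condition_uM`,
#'   `count`).
#' @examples
#' simulate_telegraph(telegraph_params(1, 0, 10, 1),
#'   n_cells = 5, t_end = 20, seed = 1
#' )
#' @export
simulate_telegraph <- function(params, n_cells, t_end, strain = "telegraph",
                               condition_uM = 0, seed = NULL) {
  if (!inherits(params, "telegraph_params")) {
    abort("`params` must be a telegraph_params object.",
      class = "burstfish_param_error"
    )
  }
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0) {
    abort("`t_end` must be a single positive time.",
      class = "burstfish_param_error"
    )
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0 ||
    n_cells != floor(n_cells)) {
    abort("`n_cells` must be a single non-negative integer.",
      class = "burstfish_param_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  counts <- telegraph_gillespie_cpp(
    as.integer(n_cells), params$k_on, params$k_off, params$k_tx,
    params$k_deg, t_end
  )
  new_count_dataset(
    cell_id = sprintf("cell_%05d", seq_len(as.integer(n_cells))),
    strain = strain, condition_uM = condition_uM, count = counts
  )
}
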