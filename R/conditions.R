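# Classed conditions so callers (and tests) can distinguish failure modes
# without matching message text.

lund_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "lundgfr_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

err_domain       <- function(msg) lund_error("lundgfr_domain_error", msg)
err_duplicate_id <- function(msg) lund_error("lundgfr_duplicate_id", msg)
err_invalid_spec <- function(msg) lund_error("lundgfr_invalid_spec", msg)
err_unknown_id   <- function(msg) lund_error("lundgfr_unknown_id", msg)
err_missing_marker   <- function(msg) lund_error("lundgfr_missing_marker", msg)
err_not_applicable   <- function(msg) lund_error("lundgfr_not_applicable", msg)
err_anchor_refused   <- function(msg) lund_error("lundgfr_anchor_refused", msg)
err_reeval_required  <- function(msg) lund_error("lundgfr_reevaluation_required", msg)
err_io <- function(msg) lund_error("lundgfr_io_error", msg)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
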