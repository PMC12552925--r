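#' Health states of the Markov model
#'
#' The cohort model has ten mutually exclusive health states:
#' 1. no radiographic disease;
#' 2. localized disease, no treatment;
#' 3. localized disease, local treatment;
#' 4. localized disease, systemic treatment;
#' 5. no radiographic disease after localized disease;
#' 6. metastatic disease, ADT + ARSI;
#' 7. metastatic disease, metastasis-directed therapy (+ systemic);
#' 8. metastatic castration-resistant prostate cancer (mCRPC);
#' 9. prostate-cancer death;
#' 10. death from other causes.
#'
#' States 9 and 10 are absorbing; only state 8 can transition to state 9;
#' only state 3 can reach state 5; metastatic states never transition back to
#' localized or disease-free states.
#'
#' @return Character vector of ten state labels, in model order.
#' @export
health_states <- function() {
  c("nrd", "loc_no_tx", "loc_local_tx", "loc_systemic", "nrd_after_local",
    "met_adt_arsi", "met_mdt", "mcrpc", "death_pca", "death_other")
}

#' Permitted transition structure
#'
#' The structural adjacency of the ten-state model: entry `[i, j]` is `TRUE`
#' when a direct transition from state `i` to state `j` is permitted
#' (including self-loops). Background mortality adds a transition from every
#' living state to state 10 and is part of the structure.
#'
#' @return A 10 x 10 logical matrix with state labels as dimnames.
#' @export
transition_adjacency <- function() {
  s <- health_states()
  adj <- matrix(FALSE, 10, 10, dimnames = list(s, s))
  allow <- function(i, j) adj[i, j] <<- TRUE
  # developing disease from radiographically negative status
  allow(1, c(1, 2, 3, 4, 6, 7, 10))
  # localized disease: progression to metastatic; local treatment may clear
  allow(2, c(2, 6, 7, 10))
  allow(3, c(3, 5, 6, 7, 10))
  allow(4, c(4, 6, 7, 10))
  # disease-free after local treatment: at risk of metastasis only
  allow(5, c(5, 6, 7, 10))
  # metastatic -> mCRPC; mCRPC -> prostate-cancer death
  allow(6, c(6, 8, 10))
  allow(7, c(7, 8, 10))
  allow(8, c(8, 9, 10))
  # absorbing
  allow(9, 9)
  allow(10, 10)
  adj
}
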