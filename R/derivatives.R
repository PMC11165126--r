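#' State of one neural mass
#'
#' Potentials (mV) and first derivatives (mV/s) of the pyramidal (`y0`),
#' excitatory (`ye`) and inhibitory (`yi`) subpopulations.  The node's local
#' field potential is `dy = ye - yi`.
#'
#' @param y0,y0d,ye,yed,yi,yid potentials and first derivatives.
#' @return an object of class `node_state` (named numeric of length 6).
#' @export
node_state <- function(y0 = 0, y0d = 0, ye = 0, yed = 0, yi = 0, yid = 0) {
  s <- c(y0 = y0, y0d = y0d, ye = ye, yed = yed, yi = yi, yid = yid)
  if (any(!is.finite(s))) stop("node state must be finite", call. = FALSE)
  class(s) <- "node_state"
  s
}

#' Time derivatives of one neural mass
#'
#' The three second-order population equations rewritten as six first-order
#' ones.  Each population is a critically damped oscillator (damping `2/tau`,
#' restoring `1/tau^2`) driven by the rate-transformed feedback of the other
#' populations and, for the excitatory population, by noise, stimulus and
#' the pre-summed coupled input from linked nodes:
#' \deqn{y_0'' = (A/\tau_e) S(y_e - y_i) - (2/\tau_e) y_0' - y_0/\tau_e^2}
#' \deqn{y_e'' = (A/\tau_e) C_2 S(C_1 y_0) + (A/\tau_e)(p + stim) + coupled
#'   - (2/\tau_e) y_e' - y_e/\tau_e^2}
#' \deqn{y_i'' = (B/\tau_i) C_4 S(C_3 y_0) - (2/\tau_i) y_i' - y_i/\tau_i^2}
#' where `S` is the node's internal transfer.  All second derivatives are in
#' mV/s^2.  With zero drive the all-zero state is an exact fixed point.
#'
#' @param s a [node_state()] (or named numeric with its six fields).
#' @param params a [node_params()].
#' @param drive list or named numeric with `p` (background noise rate, s^-1,
#'   may be negative), `stim` (stimulus rate, >= 0) and `coupled` (pre-summed
#'   weighted input from linked nodes, already multiplied by `A/tau_e`; see
#'   [coupled_input()]).
#' @return named numeric of the six derivatives
#'   `(y0d, y0dd, yed, yedd, yid, yidd)` ordered as the state fields.
#' @export
node_derivatives <- function(s, params, drive = list(p = 0, stim = 0,
                                                     coupled = 0)) {
  if (any(!is.finite(unlist(s)))) stop("state must be finite", call. = FALSE)
  dr <- as.list(drive)
  for (f in c("p", "stim", "coupled"))
    if (is.null(dr[[f]]) || !is.finite(dr[[f]]))
      stop("drive field '", f, "' must be finite", call. = FALSE)
  if (dr$stim < 0) stop("stimulus rate must be non-negative", call. = FALSE)
  S <- function(v) rate_transform(v, params$transfer_internal)
  te <- params$tau_e; ti <- params$tau_i
  ae <- params$A / te; bi <- params$B / ti
  y0 <- s[["y0"]]; y0d <- s[["y0d"]]
  ye <- s[["ye"]]; yed <- s[["yed"]]
  yi <- s[["yi"]]; yid <- s[["yid"]]
  c(y0d = y0d,
    y0dd = ae * S(ye - yi) - 2 / te * y0d - y0 / te^2,
    yed = yed,
    yedd = ae * params$C2 * S(params$C1 * y0) + ae * (dr$p + dr$stim) +
      dr$coupled - 2 / te * yed - ye / te^2,
    yid = yid,
    yidd = bi * params$C4 * S(params$C3 * y0) - 2 / ti * yid - yi / ti^2)
}

#' Scaled coupling matrix
#'
#' Raw tracer-derived weights span orders of magnitude, so by default each
#' row (target) is normalised to sum to a single global gain `G`, keeping the
#' coupled drive commensurate with the noise and stimulus terms.
#'
#' @param net a [cluster_network()].
#' @param scaling `"row_normalized"` (default; `G * W[k, ] / sum(W[k, ])`),
#'   `"raw"` (weights used as-is, times `G`), or `"user"` (caller supplies the
#'   full matrix in `user_matrix`).
#' @param G global coupling gain, default 1.
#' @param user_matrix matrix used verbatim when `scaling = "user"`.
#' @return the scaled matrix, same orientation as `net$W`.
#' @export
coupling_matrix <- function(net, scaling = c("row_normalized", "raw", "user"),
                            G = 1, user_matrix = NULL) {
  scaling <- match.arg(scaling)
  switch(scaling,
         row_normalized = {
           rs <- rowSums(net$W)
           rs[rs == 0] <- 1
           G * net$W / rs
         },
         raw = G * net$W,
         user = {
           if (is.null(user_matrix)) stop("user_matrix required", call. = FALSE)
           as.matrix(user_matrix)
         })
}

#' Coupled input to one node from the delayed outputs of linked nodes
#'
#' Each source node's delayed LFP `dy_j(t - d_kj/v)` passes through that
#' node's *output* transfer, is weighted by the scaled coupling matrix, and
#' the sum is multiplied by the target's `A_k / tau_e_k` so it adds directly
#' to the excitatory drive (same placement as noise and stimulus).
#'
#' @param delayed_lfps numeric vector, one delayed `dy_j` (mV) per source
#'   node, in network node order.
#' @param k target node index.
#' @param net a [cluster_network()].
#' @param source_params list of [node_params()], one per node.
#' @param Wbar scaled coupling matrix; default [coupling_matrix()] of `net`.
#' @return rate contribution in mV/s^2-producing units (s^-1 scaled by
#'   `A_k/tau_e_k`), ready to enter the excitatory equation unchanged.
#' @export
coupled_input <- function(delayed_lfps, k, net, source_params,
                          Wbar = coupling_matrix(net)) {
  n <- length(net$names)
  if (length(delayed_lfps) != n)
    stop("need one delayed LFP per source node (", n, ")", call. = FALSE)
  if (length(source_params) != n)
    stop("need one node_params per node", call. = FALSE)
  rates <- vapply(seq_len(n), function(j)
    rate_transform(delayed_lfps[j], source_params[[j]]$transfer_output),
    numeric(1))
  pk <- source_params[[k]]
  (pk$A / pk$tau_e) * sum(Wbar[k, ] * rates)
}

#' Per-node and cluster local field potentials
#'
#' The LFP of a node is `dy = ye - yi`; the cluster LFP is the unweighted
#' mean of the per-node LFPs at each sample.
#'
#' @param ye,yi equal-length potential traces (mV), or matrices with one row
#'   per node.
#' @return `lfp_of`: `ye - yi`; `cluster_lfp`: column means of a node-by-time
#'   LFP matrix.
#' @export
lfp_of <- function(ye, yi) {
  if (length(ye) == 0) stop("empty trace", call. = FALSE)
  if (!identical(dim(ye), dim(yi)) || length(ye) != length(yi))
    stop("ye and yi must have identical shape", call. = FALSE)
  ye - yi
}

#' @param lfp node-by-time matrix of per-node LFP traces (mV).
#' @rdname lfp_of
#' @export
cluster_lfp <- function(lfp) {
  if (length(lfp) == 0) stop("empty input", call. = FALSE)
  if (is.null(dim(lfp))) return(lfp)
  colMeans(lfp)
}
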