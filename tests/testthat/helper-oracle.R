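# Independent shortest-path oracle: iterative label correction
# (Bellman-Ford style) over the 8 neighbour shifts until fixpoint.
# Deliberately a different algorithm family from the package's
# priority-queue computation; no graph library involved.
oracle_travel_time <- function(crossing, seeds) {
  nr <- nrow(crossing); nc <- ncol(crossing)
  pass <- !is.na(crossing)
  d <- matrix(Inf, nr, nc)
  d[cbind(seeds[, 1], seeds[, 2])] <- 0
  d[!pass] <- NA_real_
  shifts <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (s in shifts) {
      dr <- s[1]; dc <- s[2]
      mult <- if (dr != 0 && dc != 0) sqrt(2) else 1
      # target rows/cols receiving a label from their (dr,dc) neighbour
      tr <- max(1, 1 + dr):min(nr, nr + dr)
      tc <- max(1, 1 + dc):min(nc, nc + dc)
      sr <- tr - dr; sc <- tc - dc
      cand <- d[sr, sc, drop = FALSE] +
        (crossing[sr, sc, drop = FALSE] + crossing[tr, tc, drop = FALSE]) / 2 * mult
      cur <- d[tr, tc, drop = FALSE]
      upd <- !is.na(cand) & !is.na(cur) & cand < cur - 1e-15
      if (any(upd)) {
        cur[upd] <- cand[upd]
        d[tr, tc] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

octile_closed_form <- function(t, dr, dc) {
  t * (pmax(abs(dr), abs(dc)) + (sqrt(2) - 1) * pmin(abs(dr), abs(dc)))
}
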