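## Brute-force flood fill (explicit-stack DFS over single voxels): the
## independent oracle for connected-component labelling.
oracle_flood_fill <- function(supra, connectivity = 6) {
  d <- dim(supra)
  nb <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
          c(0, 0, 1), c(0, 0, -1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  lab <- array(0L, d)
  cur <- 0L
  for (v in which(supra)) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    stack <- v
    lab[v] <- cur
    while (length(stack)) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ai <- arrayInd(u, d)
      for (k in seq_len(nrow(nb))) {
        p <- ai + nb[k, ]
        if (any(p < 1) || any(p > d)) next
        pi <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (supra[pi] && lab[pi] == 0L) {
          lab[pi] <- cur
          stack <- c(stack, pi)
        }
      }
    }
  }
  lab
}

## Component size multiset from a label map (order-independent comparison).
label_sizes <- function(lab) sort(tabulate(lab[lab > 0L]))
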