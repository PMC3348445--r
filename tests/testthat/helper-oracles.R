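# Brute-force oracles shared by the acceptance checks. Each re-implements
# the published procedure directly from its definition, independently of
# the package internals.

oracle_leader_acc <- function(xyz, tags, max_dist = 1.5) {
  m <- nrow(xyz)
  dmat <- as.matrix(stats::dist(xyz))
  nnls <- lapply(seq_len(m), function(i) {
    mem <- i
    for (t in setdiff(unique(tags), tags[i])) {
      cand <- which(tags == t)
      nb <- cand[which.min(dmat[i, cand])]
      if (dmat[i, nb] <= max_dist + 1e-9) mem <- c(mem, nb)
    }
    mem
  })
  done <- rep(FALSE, m)
  clusters <- list()
  while (!all(done)) {
    live <- which(!done)
    lens <- vapply(live, function(i) length(nnls[[i]]), integer(1))
    top <- live[lens == max(lens)]
    if (length(top) > 1) {
      msd <- vapply(top, function(i) {
        mem <- nnls[[i]]
        if (length(mem) < 2) 0
        else mean(dmat[mem, mem][upper.tri(dmat[mem, mem])]^2)
      }, numeric(1))
      top <- top[which.min(msd)]
    }
    mem <- nnls[[top[1]]]
    clusters[[length(clusters) + 1]] <- sort(mem)
    done[mem] <- TRUE
    for (i in which(!done)) nnls[[i]] <- setdiff(nnls[[i]], mem)
  }
  clusters
}

oracle_dp_acc <- function(a, b) {
  pa <- extract_pharmacophore(a); pb <- extract_pharmacophore(b)
  if (!length(pa) && !length(pb)) return(0)
  key <- function(p) paste(p$contributors$ligand, p$contributors$point)
  cand <- expand.grid(i = seq_along(pa), j = seq_along(pb))
  if (nrow(cand))
    cand <- cand[vapply(seq_len(nrow(cand)), function(r)
      pa[[cand$i[r]]]$kind == pb[[cand$j[r]]]$kind, logical(1)), ,
      drop = FALSE]
  if (nrow(cand)) {
    cand$T <- vapply(seq_len(nrow(cand)), function(r) {
      na <- nrow(pa[[cand$i[r]]]$contributors)
      nb <- nrow(pb[[cand$j[r]]]$contributors)
      nab <- length(intersect(key(pa[[cand$i[r]]]), key(pb[[cand$j[r]]])))
      nab / (na + nb - nab)
    }, numeric(1))
    cand$w <- vapply(seq_len(nrow(cand)), function(r) {
      na <- nrow(pa[[cand$i[r]]]$contributors)
      nb <- nrow(pb[[cand$j[r]]]$contributors)
      ((na + nb) / 2)^2
    }, numeric(1))
    cand <- cand[order(-cand$T, -cand$w, cand$i, cand$j), , drop = FALSE]
  }
  ua <- logical(length(pa)); ub <- logical(length(pb))
  num <- 0; den <- 0
  for (r in seq_len(nrow(cand))) {
    if (ua[cand$i[r]] || ub[cand$j[r]]) next
    ua[cand$i[r]] <- TRUE; ub[cand$j[r]] <- TRUE
    num <- num + cand$w[r] * cand$T[r]; den <- den + cand$w[r]
  }
  U <- sum(vapply(pa[!ua], function(p) nrow(p$contributors)^2, numeric(1))) +
    sum(vapply(pb[!ub], function(p) nrow(p$contributors)^2, numeric(1)))
  if (U + den == 0) 0 else 1 - num / (U + den)
}
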