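# shared cached SCF contexts and quadratures (built once per session)
.ctx_cache <- new.env(parent = emptyenv())

cached_ctx <- function(name, basis = "sto-3g", conv = NULL) {
  key <- paste(name, basis, if (is.null(conv)) "std" else "tight")
  if (is.null(.ctx_cache[[key]])) {
    mol <- fixtures()[[name]]$molecule
    .ctx_cache[[key]] <- if (is.null(conv)) build_scf_context(mol, basis)
      else build_scf_context(mol, basis, conv = conv)
  }
  .ctx_cache[[key]]
}

cached_quad <- function(name, K = 7L, basis = "sto-3g") {
  key <- paste("q", name, basis, K)
  if (is.null(.ctx_cache[[key]]))
    .ctx_cache[[key]] <- laplace_for_scf(cached_ctx(name, basis), K)
  .ctx_cache[[key]]
}

cached_dense_R <- function(name, K = 5L, basis = "sto-3g") {
  key <- paste("Rd", name, basis, K)
  if (is.null(.ctx_cache[[key]])) {
    ctx <- cached_ctx(name, basis)
    q <- cached_quad(name, K, basis)
    .ctx_cache[[key]] <- lapply(seq_len(q$K), function(k)
      r_dense_oracle(ctx, build_pseudodensities(ctx, q, k)))
  }
  .ctx_cache[[key]]
}

max_R_diff <- function(R1, R2) {
  max(vapply(seq_along(R1), function(k) {
    max(vapply(c("alpha", "beta"), function(sp) max(
      abs(R1[[k]][[sp]]$Rocc - R2[[k]][[sp]]$Rocc),
      abs(R1[[k]][[sp]]$Rvirt - R2[[k]][[sp]]$Rvirt)), 0))
  }, 0))
}

# spin-flipped copy of an scf context (alpha <-> beta everywhere)
flip_spins <- function(ctx) {
  swap <- function(x) list(alpha = x$beta, beta = x$alpha)
  for (f in c("F", "C", "eps", "P_occ", "P_virt", "n_occ", "h_spin"))
    ctx[[f]] <- swap(ctx[[f]])
  ctx
}
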