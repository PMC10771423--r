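# Anisotropic network model on the backbone nodes (Calpha atoms, or every
# pseudo-atom for the synthetic pockets). Unit spring constants, 12 A contact
# cutoff, residue-rigid carriage of side-chain atoms: standard elastic-network
# conventions, all exposed in the arguments.

#' Build anisotropic-network normal modes
#'
#' Assembles the 3N x 3N ANM Hessian of the harmonic contact network on the
#' model's backbone nodes (unit spring constant, contacts within `cutoff`)
#' and returns the lowest `n_modes` nontrivial modes. For a connected,
#' non-degenerate network the six rigid-body motions span the null space.
#'
#' @param model A [protein_model()].
#' @param cutoff Contact cutoff, Angstrom (default 12).
#' @param n_modes Number of nontrivial modes to keep (default 6).
#' @return An object of class `mode_set`: list with `eigenvalues` (ascending,
#'   model units), `eigenvectors` (3N x n_modes, orthonormal), `cutoff`,
#'   `n_nontrivial`, `node_indices`, and `n_zero` (size of the numerical null
#'   space).
#' @export
build_modes <- function(model, cutoff = 12, n_modes = 6) {
  nodes <- model$ca_indices
  n <- length(nodes)
  if (n < 3) abort("need at least 3 network nodes")
  X <- as.matrix(model$atoms[nodes, c("x", "y", "z")])
  D <- as.matrix(stats::dist(X))
  contact <- D <= cutoff & upper.tri(D)
  # connectivity check
  comp <- seq_len(n)
  pairs <- which(contact, arr.ind = TRUE)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1) {
    sizes <- table(comp)
    abort(sprintf(
      "elastic network is disconnected at cutoff %.1f A: %d components (sizes %s)",
      cutoff, length(sizes), paste(sizes, collapse = ", ")
    ))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    d <- X[j, ] - X[i, ]
    d2 <- sum(d^2)
    blk <- -outer(d, d) / d2
    ii <- (3 * i - 2):(3 * i)
    jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  eig <- eigen(H, symmetric = TRUE)
  ev <- rev(eig$values)
  vec <- eig$vectors[, rev(seq_len(ncol(eig$vectors))), drop = FALSE]
  tol <- max(abs(ev)) * 1e-9
  n_zero <- sum(ev < tol)
  keep <- seq(n_zero + 1, min(n_zero + n_modes, 3 * n))
  structure(
    list(
      eigenvalues = ev[keep],
      eigenvectors = vec[, keep, drop = FALSE],
      all_eigenvalues = ev,
      cutoff = cutoff,
      n_nontrivial = length(keep),
      n_zero = n_zero,
      node_indices = nodes
    ),
    class = "mode_set"
  )
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf(
    "<mode_set> %d nodes, %d nontrivial modes (null space %d), cutoff %.1f A\n",
    length(x$node_indices), x$n_nontrivial, x$n_zero, x$cutoff
  ))
  invisible(x)
}

#' Displace the backbone along a random mode combination
#'
#' Draws a random unit combination of the stored modes, scales it so the
#' root-mean-square displacement of the network nodes equals `amplitude`,
#' and moves every atom of a residue rigidly with its node.
#'
#' @param model A [protein_model()].
#' @param modes A `mode_set` from [build_modes()].
#' @param amplitude Node RMSD of the move, Angstrom (>= 0).
#' @return The displaced model.
#' @export
displace_backbone <- function(model, modes, amplitude) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (amplitude == 0) return(model)
  k <- ncol(modes$eigenvectors)
  coefs <- rnorm(k)
  coefs <- coefs / sqrt(sum(coefs^2))
  v <- as.numeric(modes$eigenvectors %*% coefs)
  n <- length(modes$node_indices)
  disp <- matrix(v, ncol = 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums(disp^2)))
  disp <- disp * (amplitude / rmsd)
  node_res <- model$atoms$res_index[modes$node_indices]
  atom_node <- match(model$atoms$res_index, node_res)
  moved <- !is.na(atom_node)
  model$atoms$x[moved] <- model$atoms$x[moved] + disp[atom_node[moved], 1]
  model$atoms$y[moved] <- model$atoms$y[moved] + disp[atom_node[moved], 2]
  model$atoms$z[moved] <- model$atoms$z[moved] + disp[atom_node[moved], 3]
  model
}

#' Write a mode set to a delimited text file
#'
#' @param modes A `mode_set`.
#' @param path Output path (tab-separated; first row eigenvalues).
#' @return `path`, invisibly.
#' @export
write_modes <- function(modes, path) {
  tab <- rbind(modes$eigenvalues, modes$eigenvectors)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     col.names = paste0("mode", seq_along(modes$eigenvalues)))
  invisible(path)
}
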