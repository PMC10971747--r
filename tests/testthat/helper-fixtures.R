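# Shared fixture builders (all in code; no binary data on disk).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Minimal hand-built structure from explicit atom rows.
manual_structure <- function(..., id = "manual") {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(type = "ATOM", eleno = i, elety = r$elety,
               alt = "", resid = r$resid, chain = r$chain,
               resno = as.integer(r$resno), insert = "",
               x = r$x, y = r$y, z = r$z, o = 1, b = 0,
               elesy = r$elesy, stringsAsFactors = FALSE)
  }))
  abmature:::new_structure(atoms, id = id)
}

atom <- function(chain, resno, resid, elety, x, y, z, elesy = "C") {
  list(chain = chain, resno = resno, resid = resid, elety = elety,
       x = x, y = y, z = z, elesy = elesy)
}

# Two single-residue chains whose closest heavy atoms are `gap` apart.
two_residue_structure <- function(gap) {
  manual_structure(
    atom("A", 1, "GLY", "CA", 0, 0, 0),
    atom("B", 1, "GLY", "CA", gap, 0, 0))
}

# Independent brute-force interface oracle: every residue pair, every heavy
# atom pair, explicit loops over a coordinate matrix. Returns sorted residue
# keys per group.
brute_force_interface <- function(structure, group_a, group_b, cutoff) {
  at <- structure$atoms[structure$atoms$elesy != "H", ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  keys <- paste0(at$chain, at$resno, at$insert)
  a_res <- unique(keys[at$chain %in% group_a])
  b_res <- unique(keys[at$chain %in% group_b])
  rows_of <- lapply(c(a_res, b_res), function(k) which(keys == k))
  names(rows_of) <- c(a_res, b_res)
  hit_a <- character(); hit_b <- character()
  for (ra in a_res) for (rb in b_res) {
    ia <- rows_of[[ra]]; ib <- rows_of[[rb]]
    dmin <- Inf
    for (i in ia) for (j in ib) {
      dmin <- min(dmin, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
    if (dmin <= cutoff) {
      hit_a <- union(hit_a, ra)
      hit_b <- union(hit_b, rb)
    }
  }
  list(a = sort(hit_a), b = sort(hit_b))
}

interface_keys <- function(map) {
  list(a = sort(paste0(map$group_a$chain, map$group_a$resno,
                       map$group_a$insert)),
       b = sort(paste0(map$group_b$chain, map$group_b$resno,
                       map$group_b$insert)))
}

# Independent sliding-window liability oracle: explicit per-position
# checks of the nine motifs, no regex.
oracle_liabilities <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  add <- function(motif, start, classes, match) {
    rows[[length(rows) + 1L]] <<- data.frame(
      motif = motif, start = start, classes = classes, match = match,
      stringsAsFactors = FALSE)
  }
  dimers <- list(NS = "deamidation;cleavage", NG = "deamidation",
                 NH = "deamidation", DS = "isomerization",
                 DG = "isomerization", DD = "isomerization",
                 DQ = "cleavage")
  for (i in seq_len(max(0, n - 1))) {
    di <- paste0(chars[i], chars[i + 1])
    if (!is.null(dimers[[di]])) add(di, i, dimers[[di]], di)
  }
  for (i in seq_len(max(0, n - 2))) {
    if (chars[i] == "N" && chars[i + 1] %in% AA20) {
      tri <- paste0(chars[i], chars[i + 1], chars[i + 2])
      if (chars[i + 2] == "T") add("NxT", i, "glycosylation", tri)
      if (chars[i + 2] == "S") add("NxS", i, "glycosylation", tri)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(), start = integer(), classes = character(),
               match = character(), stringsAsFactors = FALSE)
  out <- out[order(out$start, out$motif), ]
  rownames(out) <- NULL
  out
}

long_seq <- function(n) {
  paste(rep_len(strsplit("KVERI", "")[[1]], n), collapse = "")
}

rot_mat <- function(a, b, c) {
  Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
               byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3,
               byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Exhaustive rotation-grid + refine oracle for the minimal RMSD between two
# point sets, independent of the package's Kabsch superposition.
oracle_min_rmsd <- function(p, q) {
  pc <- scale(p, scale = FALSE)
  qc <- scale(q, scale = FALSE)
  f <- function(ang) {
    R <- rot_mat(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((qc %*% t(R) - pc)^2)))
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- f(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  stats::optim(best_ang, f)$value
}

# A planted toy round: complex, sequences, ddG tables and scan with one
# beneficial mutation known by construction.
toy_round_inputs <- function(planted_label = "L5D", improvement = 1.5,
                             seed = 42) {
  planted <- data.frame(ab_chain = c("H", "H", "L", "L"),
                        ab_resno = c(3, 6, 5, 9),
                        ag_resno = c(2, 5, 8, 11),
                        distance = c(2.8, 2.9, 2.8, 2.9))
  # liability-free sequences (no N/D dimer motifs, no alanine wild types)
  seqs_in <- list(A = "KVERIKVERIKVERI", H = "KVERIKVERI",
                  L = "KVERIKVERI")
  cx <- make_toy_complex(n_antigen = 15, n_heavy = 10, n_light = 10,
                         planted = planted, sequences = seqs_in, seed = seed)
  seqs <- as.list(attr(cx, "sequences"))
  key <- data.frame(chain = planted$ab_chain, position = planted$ab_resno)
  imp <- setNames(improvement, planted_label)
  # alanine-scan tables: every planted contact residue is significant
  ala_planted <- setNames(
    rep(-2, nrow(key)),
    vapply(seq_len(nrow(key)), function(i) {
      wt <- substr(seqs[[key$chain[i]]], key$position[i], key$position[i])
      paste0(key$chain[i], key$position[i], ifelse(wt == "A", "G", "A"))
    }, character(1)))
  ala <- simulate_ddg_tables(key, seqs, planted = ala_planted,
                             mutants = "alanine", seed = seed + 1)
  sat <- simulate_ddg_tables(key, seqs, planted = imp,
                             mutants = "saturation", seed = seed + 2)
  scan <- simulate_experimental_scan(key, key, seqs, seed = seed + 3)
  list(complex = cx, sequences = seqs, key = key, planted = planted,
       alanine = ala, saturation = sat, scan = scan,
       planted_label = planted_label)
}
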