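#' Declare a chemical species
#'
#' @param name Species identifier (no whitespace).
#' @param mu0 Standard chemical potential in units of kT. Defaults to 0, the
#'   convention used throughout the bundled networks; with `mu0 = 0` local
#'   detailed balance forces symmetric forward/backward rate constants.
#' @param chemostat Either `NULL` (dynamic species) or a nonnegative integer
#'   clamp count: the molecule number at which the species is held while the
#'   network is open.
#' @return A `crn_species` object (a light list).
#' @export
crn_species <- function(name, mu0 = 0, chemostat = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            !grepl("\\s", name))
  if (!is.null(chemostat)) {
    if (!is.numeric(chemostat) || length(chemostat) != 1L ||
        chemostat < 0 || chemostat != round(chemostat))
      stop("chemostat clamp count must be a single nonnegative integer")
    chemostat <- as.numeric(chemostat)
  }
  structure(list(name = name, mu0 = as.numeric(mu0), chemostat = chemostat),
            class = "crn_species")
}

# parse "Hi + 2 X" or "2X + B" into a named stoichiometry vector
parse_side <- function(side) {
  side <- trimws(side)
  if (!nzchar(side) || identical(side, "0")) return(stats::setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tm in terms) {
    m <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_()^]*)$", tm))[[1]]
    if (length(m) == 0L) stop("cannot parse reaction term: '", tm, "'")
    coeff <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    sp <- m[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0) + coeff
  }
  out
}

#' Declare a reversible reaction pair
#'
#' Reactions are stored as forward/backward pairs rather than as independent
#' irreversible reactions, so that the local detailed balance constraint is a
#' structural property of the network.
#'
#' @param educts,products Either strings such as `"Hi + 2 X"` or named numeric
#'   vectors of stoichiometric coefficients (forward direction).
#' @param kf,kb Strictly positive forward and backward mass-action rate
#'   constants (deterministic convention; the stochastic propensity rescales
#'   by the volume).
#' @param label Identifier for the pair; autogenerated if missing.
#' @return A `crn_reaction` object.
#' @export
crn_reaction <- function(educts, products, kf, kb, label = NULL) {
  if (is.character(educts)) educts <- parse_side(educts)
  if (is.character(products)) products <- parse_side(products)
  stopifnot(is.numeric(educts), is.numeric(products))
  if (any(educts < 0) || any(educts != round(educts)) ||
      any(products < 0) || any(products != round(products)))
    stop("stoichiometric coefficients must be nonnegative integers")
  if (!is.numeric(kf) || kf <= 0 || !is.numeric(kb) || kb <= 0)
    stop("rate constants must be strictly positive (reversibility is required)")
  structure(list(educts = educts[educts > 0], products = products[products > 0],
                 kf = as.numeric(kf), kb = as.numeric(kb),
                 label = label),
            class = "crn_reaction")
}

#' Assemble a chemical reaction network
#'
#' Validates referential integrity and thermodynamic consistency: every
#' species used in a reaction must be declared, all rate constants must be
#' positive, and each pair must satisfy local detailed balance
#' \eqn{\ln(k_f/k_b) = -\beta\, \mu_0 \cdot S} within a relative tolerance of
#' 1e-9 (with all `mu0 = 0` this forces `kf == kb`).
#'
#' @param species List of [crn_species()] declarations.
#' @param reactions List of [crn_reaction()] pairs.
#' @param volume Reaction volume V (default 1).
#' @param beta Inverse temperature in 1/kT units (default 1).
#' @return A `crn_network` object.
#' @export
crn_network <- function(species, reactions, volume = 1, beta = 1) {
  if (inherits(species, "crn_species")) species <- list(species)
  if (inherits(reactions, "crn_reaction")) reactions <- list(reactions)
  stopifnot(volume > 0, beta > 0)
  nm <- vapply(species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate species names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  for (i in seq_along(reactions)) {
    if (is.null(reactions[[i]]$label)) reactions[[i]]$label <- paste0("r", i)
  }
  labs <- vapply(reactions, function(r) r$label, character(1))
  if (anyDuplicated(labs)) stop("duplicate reaction labels")
  spec <- structure(list(species = species, reactions = reactions,
                         volume = as.numeric(volume), beta = as.numeric(beta)),
                    class = "crn_network")
  for (r in reactions) {
    used <- union(names(r$educts), names(r$products))
    unknown <- setdiff(used, nm)
    if (length(unknown))
      stop("reaction '", r$label, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
  }
  v <- validate_crn(spec)
  bad <- v$pairs$label[!v$pairs$detailed_balance_ok]
  if (length(bad))
    stop("local detailed balance violated for pair(s): ",
         paste(bad, collapse = ", "),
         " (ln(kf/kb) must equal -beta * mu0 . S)")
  spec
}

#' @export
print.crn_network <- function(x, ...) {
  nc <- sum(vapply(x$species, function(s) !is.null(s$chemostat), logical(1)))
  cat("<crn_network> ", length(x$species), " species (", nc, " chemostatted), ",
      length(x$reactions), " reversible pairs, V = ", x$volume,
      ", beta = ", x$beta, "\n", sep = "")
  invisible(x)
}

species_names <- function(spec) vapply(spec$species, function(s) s$name, character(1))

chemostat_mask <- function(spec)
  vapply(spec$species, function(s) !is.null(s$chemostat), logical(1))

clamp_counts <- function(spec) {
  cl <- vapply(spec$species, function(s) if (is.null(s$chemostat)) NA_real_ else s$chemostat,
               numeric(1))
  stats::setNames(cl, species_names(spec))
}

mu0_vector <- function(spec)
  stats::setNames(vapply(spec$species, function(s) s$mu0, numeric(1)), species_names(spec))

# stoichiometry vector over all declared species (zeros filled in)
full_stoich <- function(spec, v) {
  out <- stats::setNames(numeric(length(spec$species)), species_names(spec))
  out[names(v)] <- v
  out
}

#' Net molecule-number change of a reaction pair
#'
#' Returns the full change vector over all declared species, including entries
#' for chemostatted species; those entries are reported but never applied while
#' the network is open (the clamp re-imposes the count after each event).
#'
#' @param spec A `crn_network`.
#' @param pair Pair label or index.
#' @param direction `"forward"` or `"backward"`.
#' @return Named integer vector \eqn{S_\rho} (forward) or \eqn{-S_\rho}.
#' @export
net_change <- function(spec, pair, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  r <- get_pair(spec, pair)
  s <- full_stoich(spec, r$products) - full_stoich(spec, r$educts)
  if (direction == "backward") s <- -s
  s
}

get_pair <- function(spec, pair) {
  if (is.numeric(pair)) return(spec$reactions[[pair]])
  labs <- vapply(spec$reactions, function(r) r$label, character(1))
  i <- match(pair, labs)
  if (is.na(i)) stop("unknown reaction pair: ", pair)
  spec$reactions[[i]]
}

falling_factorial <- function(n, nu) {
  r <- 1
  if (nu == 0) return(1)
  for (i in 0:(nu - 1)) {
    if (n - i <= 0) return(0)
    r <- r * (n - i)
  }
  r
}

#' Stochastic mass-action propensity
#'
#' Evaluates \eqn{w_\rho(n) = k_\rho V \prod_i V^{-\nu_i} n_i!/(n_i-\nu_i)!}
#' with the falling factorials computed iteratively (never via full
#' factorials), returning 0 whenever any educt count is below its
#' stoichiometric requirement.
#'
#' @param spec A `crn_network`.
#' @param counts Named nonnegative molecule-count vector (a `crn_state` is
#'   also accepted).
#' @param pair Pair label or index.
#' @param direction `"forward"` or `"backward"`.
#' @return Nonnegative propensity (events per unit time).
#' @export
propensity <- function(spec, counts, pair, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  counts <- state_counts(spec, counts)
  r <- get_pair(spec, pair)
  nu <- if (direction == "forward") r$educts else r$products
  k <- if (direction == "forward") r$kf else r$kb
  w <- k * spec$volume
  for (sp in names(nu)) {
    w <- w * spec$volume^(-nu[[sp]]) * falling_factorial(counts[[sp]], nu[[sp]])
  }
  unname(w)
}

#' Validate a network's thermodynamic consistency
#'
#' Report-only diagnostics: per-pair local detailed balance residuals
#' \eqn{|\ln(k_f/k_b) + \beta \mu_0\cdot S_\rho|}, per-pair total
#' molecule-count conservation (needed for the equilibrium reference
#' concentration to cancel out of reaction free energies), and chemostat
#' sanity.
#'
#' @param spec A `crn_network` (possibly not yet fully constructed).
#' @return A list with elements `pairs` (data.frame of residuals) and
#'   `chemostats` (data.frame), of class `crn_validation`.
#' @export
validate_crn <- function(spec) {
  mu0 <- mu0_vector(spec)
  rows <- lapply(spec$reactions, function(r) {
    s <- full_stoich(spec, r$products) - full_stoich(spec, r$educts)
    lhs <- log(r$kf / r$kb)
    rhs <- -spec$beta * sum(mu0 * s)
    resid <- abs(lhs - rhs)
    data.frame(label = r$label,
               db_residual = resid,
               detailed_balance_ok = resid <= 1e-9 * max(1, abs(lhs), abs(rhs)),
               conserves_count = sum(s) == 0,
               stringsAsFactors = FALSE)
  })
  ch <- data.frame(name = species_names(spec),
                   chemostatted = chemostat_mask(spec),
                   clamp = unname(clamp_counts(spec)),
                   stringsAsFactors = FALSE)
  ch$ok <- ifelse(ch$chemostatted, !is.na(ch$clamp) & ch$clamp >= 0, is.na(ch$clamp))
  structure(list(pairs = do.call(rbind, rows), chemostats = ch),
            class = "crn_validation")
}

#' @export
print.crn_validation <- function(x, ...) {
  cat("<crn_validation>\n")
  cat("  max detailed-balance residual:", max(c(0, x$pairs$db_residual)), "\n")
  cat("  pairs conserving molecule count:", sum(x$pairs$conserves_count), "/",
      nrow(x$pairs), "\n")
  cat("  chemostats sane:", all(x$chemostats$ok), "\n")
  invisible(x)
}

#' Release all chemostat clamps
#'
#' Converts every chemostatted species into an ordinary dynamic species.
#' Callers typically initialize the released species at their former clamp
#' counts, so the closed network starts relaxing towards equilibrium from the
#' driven state.
#'
#' @param spec A `crn_network`.
#' @return The closed network. If no species is chemostatted the spec is
#'   returned unchanged with a warning.
#' @export
close_network <- function(spec) {
  if (!any(chemostat_mask(spec))) {
    warning("network has no chemostatted species; returning it unchanged")
    return(spec)
  }
  spec$species <- lapply(spec$species, function(s) { s$chemostat <- NULL; s })
  spec
}

#' Network state: molecule counts plus simulation time
#'
#' @param counts Named nonnegative integer vector of molecule numbers.
#' @param time Nonnegative scalar.
#' @return A `crn_state`.
#' @export
crn_state <- function(counts, time = 0) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0),
            time >= 0)
  structure(list(counts = counts, time = as.numeric(time)), class = "crn_state")
}

# normalize a state or named vector into a count vector aligned to spec order;
# clamps are re-imposed for open networks
state_counts <- function(spec, state, enforce_clamps = TRUE) {
  counts <- if (inherits(state, "crn_state")) state$counts else state
  nm <- species_names(spec)
  out <- stats::setNames(numeric(length(nm)), nm)
  extra <- setdiff(names(counts), nm)
  if (length(extra)) stop("state contains undeclared species: ",
                          paste(extra, collapse = ", "))
  out[names(counts)] <- counts  # species absent from the state default to 0
  if (enforce_clamps) {
    cm <- chemostat_mask(spec)
    out[cm] <- clamp_counts(spec)[cm]
  }
  if (any(out < 0)) stop("negative molecule count")
  out
}

# --- reaction-list text format ------------------------------------------------

format_side <- function(v) {
  if (!length(v)) return("0")
  paste(vapply(names(v), function(sp) {
    if (v[[sp]] == 1) sp else paste(v[[sp]], sp)
  }, character(1)), collapse = " + ")
}

# shortest decimal that round-trips to the same double
fmt_num <- function(x) {
  for (d in 1:17) {
    s <- format(x, digits = d, trim = TRUE, scientific = NA)
    if (as.numeric(s) == x) return(s)
  }
  s
}

#' Serialize a network to the reaction-list text format
#'
#' Canonical ordering: `volume`, `beta`, species (insertion order), reactions
#' (insertion order). The output round-trips losslessly through
#' [parse_network()].
#'
#' @param spec A `crn_network`.
#' @param file Optional path; when `NULL` the document is returned as a
#'   character scalar.
#' @export
write_network <- function(spec, file = NULL) {
  lines <- c(paste("volume", fmt_num(spec$volume)),
             paste("beta", fmt_num(spec$beta)))
  for (s in spec$species) {
    ln <- paste("species", s$name)
    if (!is.null(s$chemostat)) ln <- paste(ln, "chemostat", fmt_num(s$chemostat))
    if (s$mu0 != 0) ln <- paste(ln, "mu0", fmt_num(s$mu0))
    lines <- c(lines, ln)
  }
  for (r in spec$reactions) {
    lines <- c(lines, paste0("reaction ", format_side(r$educts), " <-> ",
                             format_side(r$products), " ; kf=", fmt_num(r$kf),
                             " kb=", fmt_num(r$kb), " label=", r$label))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  writeLines(lines, file)
  invisible(txt)
}

#' Parse a reaction-list document
#'
#' Line-oriented grammar: `species <name> [chemostat <count>] [mu0 <float>]`,
#' `reaction <educts> <-> <products> ; kf=<float> kb=<float> [label=<id>]`,
#' `volume <float>`, `beta <float>`, `#` comments. Educt/product sides are
#' `+`-separated `<coeff> <species>` terms.
#'
#' @param text Document as a single string, a character vector of lines, or a
#'   file path (when `file = TRUE`).
#' @param file Logical; treat `text` as a path.
#' @return A validated `crn_network`.
#' @export
parse_network <- function(text, file = FALSE) {
  lines <- if (file) readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  species <- list(); reactions <- list(); volume <- 1; beta <- 1
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    err <- function(msg) stop("line ", i, ": ", msg, " ['", lines[[i]], "']")
    if (grepl("^volume\\s", ln)) {
      volume <- as.numeric(trimws(sub("^volume", "", ln)))
      if (is.na(volume) || volume <= 0) err("volume must be a positive number")
    } else if (grepl("^beta\\s", ln)) {
      beta <- as.numeric(trimws(sub("^beta", "", ln)))
      if (is.na(beta) || beta <= 0) err("beta must be a positive number")
    } else if (grepl("^species\\s", ln)) {
      toks <- strsplit(trimws(sub("^species", "", ln)), "\\s+")[[1]]
      if (!length(toks)) err("species line needs a name")
      nm <- toks[[1]]; toks <- toks[-1]
      chem <- NULL; mu0 <- 0
      while (length(toks)) {
        if (toks[[1]] == "chemostat") {
          if (length(toks) < 2) err("chemostat needs a count")
          chem <- as.numeric(toks[[2]])
          if (is.na(chem) || chem < 0) err("chemostat count must be nonnegative")
          toks <- toks[-(1:2)]
        } else if (toks[[1]] == "mu0") {
          if (length(toks) < 2) err("mu0 needs a value")
          mu0 <- as.numeric(toks[[2]])
          if (is.na(mu0)) err("mu0 must be numeric")
          toks <- toks[-(1:2)]
        } else err(paste0("unknown species attribute '", toks[[1]], "'"))
      }
      species <- c(species, list(crn_species(nm, mu0 = mu0, chemostat = chem)))
    } else if (grepl("^reaction\\s", ln)) {
      body <- trimws(sub("^reaction", "", ln))
      halves <- strsplit(body, ";", fixed = TRUE)[[1]]
      if (length(halves) != 2) err("reaction line needs '; kf=... kb=...'")
      eq <- strsplit(halves[[1]], "<->", fixed = TRUE)[[1]]
      if (length(eq) != 2) err("reaction needs '<->'")
      kf <- NA; kb <- NA; label <- NULL
      for (tok in strsplit(trimws(halves[[2]]), "\\s+")[[1]]) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2) err(paste0("cannot parse parameter '", tok, "'"))
        switch(kv[[1]],
               kf = { kf <- as.numeric(kv[[2]]) },
               kb = { kb <- as.numeric(kv[[2]]) },
               label = { label <- kv[[2]] },
               err(paste0("unknown reaction parameter '", kv[[1]], "'")))
      }
      if (is.na(kf) || kf <= 0 || is.na(kb) || kb <= 0)
        err("rate constants must be positive numbers")
      rx <- try(crn_reaction(eq[[1]], eq[[2]], kf = kf, kb = kb, label = label),
                silent = TRUE)
      if (inherits(rx, "try-error")) err(attr(rx, "condition")$message)
      reactions <- c(reactions, list(rx))
    } else err("unrecognized directive")
  }
  crn_network(species, reactions, volume = volume, beta = beta)
}

#' Fingerprint a network
#'
#' Polynomial rolling hash (mod 2^31 - 1) of the canonical reaction-list
#' serialization; used to tie simulation output back to the exact network
#' that produced it.
#'
#' @param spec A `crn_network`.
#' @return Hex string.
#' @export
network_fingerprint <- function(spec) {
  bytes <- utf8ToInt(write_network(spec))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# compiled representation consumed by the C++ SSA core and the ODE/CME code:
# directions are interleaved, dir 2p-1 = forward of pair p, dir 2p = backward
crn_compile <- function(spec) {
  nm <- species_names(spec)
  m <- length(nm); P <- length(spec$reactions)
  nu <- matrix(0L, 2L * P, m, dimnames = list(NULL, nm))
  dS_full <- matrix(0L, 2L * P, m, dimnames = list(NULL, nm))
  k <- numeric(2L * P)
  dir_pair <- integer(2L * P)
  dir_forward <- logical(2L * P)
  for (p in seq_len(P)) {
    r <- spec$reactions[[p]]
    e <- full_stoich(spec, r$educts); pr <- full_stoich(spec, r$products)
    f <- 2L * p - 1L; b <- 2L * p
    nu[f, ] <- e; nu[b, ] <- pr
    dS_full[f, ] <- pr - e; dS_full[b, ] <- e - pr
    k[f] <- r$kf; k[b] <- r$kb
    dir_pair[c(f, b)] <- p
    dir_forward[f] <- TRUE
  }
  cm <- chemostat_mask(spec)
  dS <- dS_full
  dS[, cm] <- 0L
  # k * V^(1 - sum nu): constant prefactor of each direction's propensity
  kV <- k * spec$volume^(1 - rowSums(nu))
  list(nu = nu, dS = dS, dS_full = dS_full, kV = kV, k = k,
       species = nm, chemostatted = cm, clamps = clamp_counts(spec),
       pair_labels = vapply(spec$reactions, function(r) r$label, character(1)),
       dir_pair = dir_pair, dir_forward = dir_forward,
       volume = spec$volume, beta = spec$beta)
}
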