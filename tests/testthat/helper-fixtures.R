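# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cache <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# ideal antiparallel i+j=39 dimer, Abeta12-24 spans 16-22 / 17-23
fx_ap39 <- function() fx_cache("ap39", function()
  build_dimer_conformation(
    dimer_fixture_spec("antiparallel", 39, span_a = c(16, 22),
                       span_b = c(17, 23)), seed = 1))

# two fully hydrogen-bonded 7-residue strands (KLVFFAE, 16-22), i+j=38
fx_short38 <- function() fx_cache("short38", function()
  build_dimer_conformation(
    dimer_fixture_spec("antiparallel", 38, span_a = c(16, 22),
                       span_b = c(16, 22), sequence = "KLVFFAE",
                       first_residue_number = 16L), seed = 1))

# single-chain ideal alpha helix (13 ALA) and extended strand
fx_single_chain <- function(phi, psi, key) fx_cache(key, function() {
  bb <- dimerscope:::build_backbone(rep(phi, 13), rep(psi, 13))
  at <- do.call(rbind, lapply(1:13, function(i)
    data.frame(chain = "A", resno = 11L + i, resid = "ALA",
               elety = c("N", "CA", "C", "O", "CB"),
               stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(1:13, function(i)
    rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ], bb$CB[i, ])))
  dimer_ensemble(at, matrix(as.numeric(t(xyz)) / 10, nrow = 1))
})

fx_helix <- function() fx_single_chain(-57, -47, "helix")

fx_extended <- function() fx_cache("extended", function() {
  bb <- dimerscope:::.ideal_strand(13)
  at <- do.call(rbind, lapply(1:13, function(i)
    data.frame(chain = "A", resno = 11L + i, resid = "ALA",
               elety = c("N", "CA", "C", "O", "CB"),
               stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(1:13, function(i)
    rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ], bb$CB[i, ])))
  dimer_ensemble(at, matrix(as.numeric(t(xyz)) / 10, nrow = 1))
})

# dimer with the two chains pulled far apart (no inter-chain contacts)
fx_separated <- function() fx_cache("separated", function() {
  ens <- fx_ap39()
  xyz <- ens$xyz
  bidx <- which(ens$atoms$chain == "B")
  cols <- 3 * (bidx - 1) + 1
  xyz[, cols] <- xyz[, cols] + 5       # +5 nm in x
  dimer_ensemble(ens$atoms, xyz)
})

# reference DSSP (mdtraj) simplified letters for the first model of each
# PDB file; one python invocation for the whole batch
dssp_oracle <- function(paths) {
  script <- paste(
    "import mdtraj as md, sys",
    "for f in sys.argv[1:]:",
    "    t = md.load(f)",
    "    print(''.join(md.compute_dssp(t, simplified=True)[0]))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), paths), stdout = TRUE)
  lapply(out, function(s) strsplit(s, "")[[1]])
}

# map this package's 4-class labels onto mdtraj's simplified H/E/C
simplify_classes <- function(classes)
  c(beta = "E", helix = "H", bend_turn = "C", coil = "C")[classes]
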