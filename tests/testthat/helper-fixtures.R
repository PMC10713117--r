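## Shared fixtures: PDB text builders and small configs.

## One fixed-column PDB ATOM/HETATM record (wwPDB v3.3 layout).
pdbLine <- function(record = "ATOM", serial, name, resn = "ALA", chain = "A",
                    resi = 1L, x, y, z, element = "C", altLoc = " ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altLoc, resn, chain, resi, x, y, z,
          1.00, 0.00, element)
}

## Two chains (A: 3 atoms, B: 2 atoms) plus a HETATM water.
twoChainPdb <- function() {
  paste(c(
    pdbLine(serial = 1L, name = "N",  chain = "A", x = 0,   y = 0, z = 0, element = "N"),
    pdbLine(serial = 2L, name = "CA", chain = "A", x = 1.5, y = 0, z = 0, element = "C"),
    pdbLine(serial = 3L, name = "C",  chain = "A", x = 3.0, y = 0, z = 0, element = "C"),
    pdbLine(serial = 4L, name = "CA", chain = "B", resi = 2L, x = 0, y = 5, z = 0, element = "C"),
    pdbLine(serial = 5L, name = "O",  chain = "B", resi = 2L, x = 1, y = 5, z = 0, element = "O"),
    pdbLine("HETATM", serial = 6L, name = "O", resn = "HOH", chain = "A",
            resi = 9L, x = 9, y = 9, z = 9, element = "O"),
    "END"), collapse = "\n")
}

## One atom duplicated under altlocs A and B plus a plain atom.
altlocPdb <- function() {
  paste(c(
    pdbLine(serial = 1L, name = "CA", x = 0, y = 0, z = 0, altLoc = "A"),
    pdbLine(serial = 2L, name = "CA", x = 0.2, y = 0, z = 0, altLoc = "B"),
    pdbLine(serial = 3L, name = "CB", x = 2, y = 0, z = 0),
    "END"), collapse = "\n")
}

## Chain with one iron atom among carbons.
fePdb <- function() {
  paste(c(
    pdbLine(serial = 1L, name = "CA", x = 0, y = 0, z = 0),
    pdbLine(serial = 2L, name = "FE", resn = "HEM", x = 2, y = 0, z = 0,
            element = "FE"),
    "END"), collapse = "\n")
}

## Desk-scale configs used across the learning tests.
tinySurfaceConfig <- function(targetPoints = 128L) {
  SurfaceConfig(targetPoints = targetPoints)
}

tinyModelConfig <- function() {
  ModelConfig(d = 64L, encoderDepth = 2L, encoderHeads = 4L,
              decoderDepth = 2L, decoderHeads = 4L,
              g = 32L, kPrime = 16L, m = 0.6)
}

## A very small config for gradient checks.
microModelConfig <- function() {
  ModelConfig(d = 16L, encoderDepth = 2L, encoderHeads = 2L,
              decoderDepth = 2L, decoderHeads = 2L,
              g = 8L, kPrime = 8L, m = 0.5, tokHidden = 16L, mpHidden = 8L)
}
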