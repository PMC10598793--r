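# Shared fixtures, built in code and memoized per test run.

.fx <- new.env(parent = emptyenv())

# Curated molecules (all <= 12 heavy atoms) covering fused, spiro and
# bridged rings, exocyclic double bonds, ring-ring bonds, bridging acyclic
# atoms, single-atom substituents, charges and triple bonds.
curated_molecules <- function() c(
  # acyclic only
  "C", "CC", "CCC", "CCO", "C#N", "CC(C)C", "CC(C)(C)C", "OCCO", "NCCN",
  "C#CC", "CC=O", "ClCCl",
  # single rings, bare and substituted
  "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "c1ccccc1", "c1ccncc1",
  "c1ccoc1", "c1cc[nH]c1", "C1CCOC1", "C1CCNC1", "C1CCSC1",
  "Cc1ccccc1", "COc1ccccc1", "Nc1ccccc1", "Fc1ccccc1", "Clc1ccccc1",
  "Cc1ccc(C)cc1", "Cc1ccc(N)cc1", "CCc1ccccc1", "CCCc1ccccc1",
  "OCc1ccccc1", "NCc1ccncc1", "CC1CCCCC1C", "CC1(C)CCCC1",
  # exocyclic double bonds
  "O=C1CCCC1", "O=C1CCCCC1", "C=C1CCCC1", "O=C1CCC(=O)C1", "N=C1CCCC1",
  "O=C1CCCN1", "O=S1(=O)CCCC1",
  # fused, spiro, bridged
  "c1ccc2ccccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "C1CCC2CCCCC2C1",
  "C1CC2(C1)CCC2", "C1CC2(CC1)CCCC2", "C1CC2CCC1C2", "C1CC2CCC1CC2",
  "C1CC2CCC(C1)O2", "C1CC12CC2", "C1CN2CCC1CC2",
  # ring-ring single bonds (one RF by construction)
  "c1ccc(-c2ccccc2)cc1", "C1CC(C1)C1CC1", "c1ccc(C2CC2)cc1",
  # bridging acyclic atoms between two ring systems (duplication rule)
  "C(C1CC1)C1CC1", "C(c1ccccc1)C1CC1", "OC(C1CC1)C1CC1", "N(C1CC1)C1CC1",
  "C1CC1CC1CC1", "C1CC1OC1CC1",
  # charged species
  "C[N+](C)(C)C", "[NH3+]CCO", "[O-]C(=O)C", "C[N+]1(C)CCCC1",
  "[O-]c1ccccc1",
  # salts / multi-component (largest component rule)
  "C1CC1.Cl", "Cc1ccccc1.O", "[Na+].[O-]C(=O)c1ccccc1",
  # triple bonds on and off rings
  "N#Cc1ccccc1", "C#CC1CC1", "CC#CC",
  # heteroatom-rich
  "OC1OC(O)C(O)C1O", "NC1CCNCC1N", "FC1(F)CCC1", "S1CCSCC1"
)

# Deduplicated molecule set of >= 500 structures (<= 12 heavy atoms) for
# oracle-equivalence testing: curated cases plus generated libraries,
# including bridge-mode molecules exercising the duplication rule.
fixture_molecules <- function() {
  if (!is.null(.fx$molecules)) return(.fx$molecules)
  lib1 <- molfrag::generate_library(molfrag::library_spec(
    800, seed = 20260101,
    rf_alphabet = c("C1CC1", "C1CCC1", "C1CCCC1", "c1ccccc1", "c1ccncc1",
                    "C1CCOC1", "C1CCNC1", "C1CCSC1", "c1ccoc1", "c1cc[nH]c1",
                    "C1CCCCC1", "C1COCC1"),
    af_alphabet = c("C", "CC", "O", "N", "F", "Cl", "CO", "C#N", "C=O"),
    max_substituents = 2
  ))
  lib2 <- molfrag::generate_library(molfrag::library_spec(
    300, seed = 20260102, bridge = TRUE,
    rf_alphabet = c("C1CC1", "C1CCC1", "C1CCCC1", "C1CCOC1", "C1CCNC1", "c1ccoc1")
  ))
  lib3 <- molfrag::generate_library(molfrag::library_spec(
    500, seed = 20260103, max_substituents = 4,
    rf_alphabet = c("C1CCC1", "c1ccccc1", "C1CCOC1", "c1ccncc1", "C1CCNC1"),
    af_alphabet = c("C", "CC", "CCC", "O", "N", "CO", "OC", "CCO", "C#N",
                    "C=O", "CN", "F", "Cl")
  ))
  mols <- unique(c(curated_molecules(), lib1$smiles, lib2$smiles, lib3$smiles))
  mols <- mols[vapply(mols, function(s) molfrag::heavy_atom_count(s) <= 12, logical(1))]
  .fx$molecules <- mols
  mols
}

# A pool of fragment SMILES (RFs and AFs) derived from the fixture set,
# used for similarity tests.
fixture_fragments <- function() {
  if (!is.null(.fx$fragments)) return(.fx$fragments)
  fr <- molfrag::fragment_collection(fixture_molecules()[1:150])
  .fx$fragments <- unique(fr$smiles)
  .fx$fragments
}
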