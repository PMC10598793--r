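"""Synthetic accessibility (SAscore) and natural-product likeness (NPscore)
for SMILES read from stdin, one per line. Output: SMILES<TAB>sa<TAB>np.

Uses the published RDKit Contrib scorers and their published contribution
data. Exits non-zero with a message on stderr if RDKit or its contribution
data are unavailable (callers must treat that as a configuration error)."""
import sys
import os

try:
    from rdkit import Chem
    from rdkit import RDLogger
    from rdkit.Chem import RDConfig
except Exception as exc:  # pragma: no cover
    sys.stderr.write("RDKit unavailable: %s\n" % exc)
    sys.exit(3)

RDLogger.DisableLog("rdApp.*")

sa_dir = os.path.join(RDConfig.RDContribDir, "SA_Score")
np_dir = os.path.join(RDConfig.RDContribDir, "NP_Score")
for d, name in ((sa_dir, "SA_Score"), (np_dir, "NP_Score")):
    if not os.path.isdir(d):
        sys.stderr.write("RDKit Contrib %s directory missing: %s\n" % (name, d))
        sys.exit(3)
sys.path.extend([sa_dir, np_dir])

import sascorer  # noqa: E402
import npscorer  # noqa: E402

np_model = npscorer.readNPModel()

for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        print("%s\tNA\tNA" % smi)
        continue
    sa = sascorer.calculateScore(mol)
    np_ = npscorer.scoreMol(mol, np_model)
    print("%s\t%.6f\t%.6f" % (smi, sa, np_))
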