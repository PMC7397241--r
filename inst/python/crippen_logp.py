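"""Wildman-Crippen logP oracle used by the synthetic-library generator.

Reads "SMILES id" lines from a file and prints "id\tlogp" per molecule.
Kept separate from the package's own descriptor path (OpenBabel) so that
planted ground truth never flows through the code under test.
"""

import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Crippen

RDLogger.DisableLog("rdApp.*")

with open(sys.argv[1]) as fh:
    for line in fh:
        parts = line.split()
        if not parts:
            continue
        mol = Chem.MolFromSmiles(parts[0])
        mol_id = parts[1] if len(parts) > 1 else parts[0]
        if mol is None:
            print(f"{mol_id}\tnan")
        else:
            print(f"{mol_id}\t{Crippen.MolLogP(mol)!r}")
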