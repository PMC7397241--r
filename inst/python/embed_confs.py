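"""Seeded conformer embedding: ETKDG + MMFF94, lowest-energy conformer.

Reads a SMILES file (one "SMILES id" per line), embeds n_confs conformers
per molecule with a fixed random seed, minimizes each with MMFF94, and
writes the lowest-energy conformer per molecule to an SDF (explicit
hydrogens kept, MMFF94 energy in kcal/mol stored in the `energy` field).
A status line "id\tok|fail\treason" per molecule goes to stdout.
"""

import argparse
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def embed_one(smiles, n_confs, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None, None, "unparseable"
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    params.useRandomCoords = False
    conf_ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_confs, params=params)
    if len(conf_ids) == 0:
        params.useRandomCoords = True
        conf_ids = AllChem.EmbedMultipleConfs(mol, numConfs=n_confs,
                                              params=params)
    if len(conf_ids) == 0:
        return None, None, "embedding_failed"
    try:
        results = AllChem.MMFFOptimizeMoleculeConfs(mol, mmffVariant="MMFF94")
    except Exception:
        return None, None, "minimization_failed"
    energies = [e for _, e in results]
    best = min(range(len(conf_ids)), key=lambda i: energies[i])
    return mol, (conf_ids[best], energies[best]), "ok"


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("smi_file")
    ap.add_argument("--nconfs", type=int, default=10)
    ap.add_argument("--seed", type=int, default=42)
    ap.add_argument("--out", required=True)
    args = ap.parse_args()

    writer = Chem.SDWriter(args.out)
    with open(args.smi_file) as fh:
        for line in fh:
            parts = line.split()
            if not parts:
                continue
            smiles, mol_id = parts[0], parts[1] if len(parts) > 1 else parts[0]
            mol, best, status = embed_one(smiles, args.nconfs, args.seed)
            if status != "ok":
                print(f"{mol_id}\tfail\t{status}")
                continue
            conf_id, energy = best
            mol.SetProp("_Name", mol_id)
            mol.SetProp("energy", repr(energy))
            writer.write(mol, confId=conf_id)
            print(f"{mol_id}\tok\t{energy!r}")
    writer.close()


if __name__ == "__main__":
    main()
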