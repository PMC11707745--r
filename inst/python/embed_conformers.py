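"""Seedable 3D conformer embedding bridge.

Reads {"smiles": [...], "seed": int} as JSON on stdin and writes a JSON list
with one entry per molecule: {"ok": bool, "error": str|None,
"symbols": [...], "positions": [[x,y,z], ...], "energy": float}.
Embedding is ETKDG distance geometry followed by MMFF94 minimization; the
fixed seed makes the coordinates fully reproducible.
"""
import json
import sys


def main() -> int:
    payload = json.load(sys.stdin)
    smiles_list = payload["smiles"]
    seed = int(payload.get("seed", 42))
    try:
        from rdkit import Chem
        from rdkit.Chem import AllChem
        from rdkit import RDLogger
        RDLogger.DisableLog("rdApp.*")
    except ImportError as exc:  # rdkit missing: report per molecule
        json.dump([{"ok": False, "error": f"rdkit unavailable: {exc}"}
                   for _ in smiles_list], sys.stdout)
        return 0

    results = []
    for smi in smiles_list:
        entry = {"ok": False, "error": None, "symbols": None,
                 "positions": None, "energy": None}
        try:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                raise ValueError("unparsable SMILES")
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            cid = AllChem.EmbedMolecule(mol, params)
            if cid < 0:
                params.useRandomCoords = True
                cid = AllChem.EmbedMolecule(mol, params)
            if cid < 0:
                raise ValueError("embedding failed")
            props = AllChem.MMFFGetMoleculeProperties(mol)
            if props is None:
                raise ValueError("no MMFF94 parameters for this molecule")
            AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
            ff = AllChem.MMFFGetMoleculeForceField(mol, props)
            conf = mol.GetConformer()
            entry.update(
                ok=True,
                symbols=[a.GetSymbol() for a in mol.GetAtoms()],
                positions=[list(conf.GetAtomPosition(i))
                           for i in range(mol.GetNumAtoms())],
                energy=ff.CalcEnergy(),
            )
        except Exception as exc:  # noqa: BLE001 - reported to the caller
            entry["error"] = str(exc)
        results.append(entry)
    json.dump(results, sys.stdout)
    return 0


if __name__ == "__main__":
    sys.exit(main())
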