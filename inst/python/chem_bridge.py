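"""RDKit helper used by the R package for the chemistry it cannot do natively:
SMILES parsing, 3D embedding (ETKDG + MMFF minimization), Gasteiger partial
charges, SMARTS substructure matching, and MOL2 reading.

Protocol: a single JSON request on stdin, a single JSON response on stdout.
Every response carries "ok": true/false; failures put a message in "error".
Atom indices in responses are 0-based (the R side converts).
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def _mol_to_dict(mol, mol_id):
    conf = mol.GetConformer() if mol.GetNumConformers() else None
    atoms = []
    for a in mol.GetAtoms():
        if conf is not None:
            p = conf.GetAtomPosition(a.GetIdx())
            xyz = [p.x, p.y, p.z]
        else:
            xyz = [0.0, 0.0, 0.0]
        q = a.GetDoubleProp("_GasteigerCharge") if a.HasProp("_GasteigerCharge") else 0.0
        atoms.append({"element": a.GetSymbol(), "xyz": xyz, "charge": q,
                      "fcharge": a.GetFormalCharge()})
    bonds = [[b.GetBeginAtomIdx(), b.GetEndAtomIdx(), b.GetBondTypeAsDouble()]
             for b in mol.GetBonds()]
    return {"id": mol_id, "atoms": atoms, "bonds": bonds,
            "formal_charge": Chem.GetFormalCharge(mol)}


def _embed(mol, seed):
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    if AllChem.EmbedMolecule(mol, params) != 0:
        # retry with random coords before giving up
        params.useRandomCoords = True
        if AllChem.EmbedMolecule(mol, params) != 0:
            return None
    try:
        AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
    except Exception:
        AllChem.UFFOptimizeMolecule(mol, maxIters=2000)
    return mol


def op_embed_smiles(req):
    out = []
    seed = req.get("seed", 20120608)
    for i, rec in enumerate(req["records"]):
        smi, mol_id = rec["smiles"], rec.get("id") or ("mol%d" % (i + 1))
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            raise ValueError("record %d (%s): unparseable SMILES %r" % (i + 1, mol_id, smi))
        mol = _embed(mol, seed)
        if mol is None:
            raise ValueError("record %d (%s): no embeddable conformer" % (i + 1, mol_id))
        AllChem.ComputeGasteigerCharges(mol)
        out.append(_mol_to_dict(mol, mol_id))
    return {"molecules": out}


def op_gasteiger(req):
    mol = Chem.MolFromMolBlock(req["molblock"], removeHs=False)
    if mol is None:
        raise ValueError("unparseable molblock")
    for a in mol.GetAtoms():
        if a.GetNumRadicalElectrons() > 0:
            raise ValueError("radical atom at index %d (%s)" % (a.GetIdx(), a.GetSymbol()))
    AllChem.ComputeGasteigerCharges(mol)
    charges = [a.GetDoubleProp("_GasteigerCharge") for a in mol.GetAtoms()]
    if any(q != q for q in charges):
        bad = next(i for i, q in enumerate(charges) if q != q)
        raise ValueError("charge undefined for atom %d (%s)" %
                         (bad, mol.GetAtomWithIdx(bad).GetSymbol()))
    return {"charges": charges, "formal_charge": Chem.GetFormalCharge(mol)}


def op_smarts_match(req):
    mol = Chem.MolFromMolBlock(req["molblock"], removeHs=False)
    if mol is None:
        raise ValueError("unparseable molblock")
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        raise ValueError("invalid SMARTS %r" % req["smarts"])
    matches = mol.GetSubstructMatches(patt, uniquify=True, maxMatches=256)
    return {"matches": [list(m) for m in matches]}


def op_read_mol2(req):
    mol = Chem.MolFromMol2File(req["path"], removeHs=False)
    if mol is None:
        raise ValueError("unparseable MOL2 file: %s" % req["path"])
    name = mol.GetProp("_Name") if mol.HasProp("_Name") else None
    return {"molecules": [_mol_to_dict(mol, name)]}


OPS = {"embed_smiles": op_embed_smiles, "gasteiger": op_gasteiger,
       "smarts_match": op_smarts_match, "read_mol2": op_read_mol2}


def main():
    req = json.load(sys.stdin)
    try:
        res = OPS[req["op"]](req)
        res["ok"] = True
    except Exception as exc:  # report, never traceback-dump
        res = {"ok": False, "error": str(exc)}
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
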