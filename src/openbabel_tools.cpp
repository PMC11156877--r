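// Thin interface to Open Babel: molecule perception, SMARTS matching with
// atom indices, canonicalization, InChIKey, descriptors and 3D building.
// All molecular-graph editing lives on the R side; this layer only converts.
#include <Rcpp.h>
#include <openbabel/mol.h>
#include <openbabel/atom.h>
#include <openbabel/bond.h>
#include <openbabel/ring.h>
#include <openbabel/obconversion.h>
#include <openbabel/parsmart.h>
#include <openbabel/descriptor.h>
#include <openbabel/builder.h>
#include <openbabel/forcefield.h>
#include <openbabel/obiter.h>
#include <openbabel/oberror.h>
#include <openbabel/elements.h>
#include <openbabel/generic.h>

using namespace Rcpp;
using namespace OpenBabel;

namespace {

struct QuietBabel {
  QuietBabel() { obErrorLog.SetOutputLevel(obError); obErrorLog.StopLogging(); }
};
static QuietBabel quiet_once;

bool read_smiles(OBMol &mol, const std::string &smi) {
  OBConversion conv;
  if (!conv.SetInFormat("smi")) return false;
  return conv.ReadString(&mol, smi) && mol.NumAtoms() > 0;
}

std::string write_format(OBMol &mol, const char *fmt) {
  OBConversion conv;
  if (!conv.SetOutFormat(fmt)) return "";
  return conv.WriteString(&mol, true);
}

} // namespace

// [[Rcpp::export(name = ".ob_smarts_valid")]]
LogicalVector ob_smarts_valid(CharacterVector smarts) {
  LogicalVector out(smarts.size());
  for (R_xlen_t i = 0; i < smarts.size(); ++i) {
    OBSmartsPattern pat;
    out[i] = pat.Init(as<std::string>(smarts[i]));
  }
  return out;
}

// [[Rcpp::export(name = ".ob_cansmi")]]
CharacterVector ob_cansmi(CharacterVector smiles) {
  CharacterVector out(smiles.size());
  for (R_xlen_t i = 0; i < smiles.size(); ++i) {
    OBMol mol;
    out[i] = read_smiles(mol, as<std::string>(smiles[i]))
      ? write_format(mol, "can") : "";
  }
  return out;
}

// [[Rcpp::export(name = ".ob_inchikey")]]
CharacterVector ob_inchikey(CharacterVector smiles) {
  CharacterVector out(smiles.size());
  for (R_xlen_t i = 0; i < smiles.size(); ++i) {
    OBMol mol;
    out[i] = read_smiles(mol, as<std::string>(smiles[i]))
      ? write_format(mol, "inchikey") : "";
  }
  return out;
}

// [[Rcpp::export(name = ".ob_molblock_to_cansmi")]]
std::string ob_molblock_to_cansmi(std::string molblock) {
  OBMol mol;
  OBConversion conv;
  if (!conv.SetInFormat("mol")) return "";
  if (!conv.ReadString(&mol, molblock) || mol.NumAtoms() == 0) return "";
  return write_format(mol, "can");
}

// Atom/bond tables of a perceived molecule. Bond orders are kekulized
// (Open Babel stores Kekule orders after SMILES input), so the tables can be
// written back as a V2000 MOL block without aromatic-bond bookkeeping.
// [[Rcpp::export(name = ".ob_mol_graph")]]
List ob_mol_graph(std::string smiles, bool addh) {
  OBMol mol;
  if (!read_smiles(mol, smiles)) return List::create(_["ok"] = false);
  if (addh) mol.AddHydrogens();
  const int n = mol.NumAtoms();
  CharacterVector elem(n);
  IntegerVector z(n), charge(n), nh(n), degree(n);
  LogicalVector arom(n), inring(n);
  int i = 0;
  FOR_ATOMS_OF_MOL(a, mol) {
    elem[i] = OBElements::GetSymbol(a->GetAtomicNum());
    z[i] = a->GetAtomicNum();
    charge[i] = a->GetFormalCharge();
    arom[i] = a->IsAromatic();
    inring[i] = a->IsInRing();
    nh[i] = a->ExplicitHydrogenCount() + a->GetImplicitHCount();
    degree[i] = a->GetExplicitDegree();
    ++i;
  }
  const int m = mol.NumBonds();
  IntegerVector from(m), to(m), order(m);
  LogicalVector barom(m), bring(m);
  int j = 0;
  FOR_BONDS_OF_MOL(b, mol) {
    from[j] = b->GetBeginAtomIdx();
    to[j] = b->GetEndAtomIdx();
    order[j] = b->GetBondOrder();
    barom[j] = b->IsAromatic();
    bring[j] = b->IsInRing();
    ++j;
  }
  return List::create(
    _["ok"] = true,
    _["atoms"] = DataFrame::create(
      _["elem"] = elem, _["z"] = z, _["charge"] = charge, _["arom"] = arom,
      _["in_ring"] = inring, _["nh"] = nh, _["degree"] = degree,
      _["stringsAsFactors"] = false),
    _["bonds"] = DataFrame::create(
      _["from"] = from, _["to"] = to, _["order"] = order,
      _["arom"] = barom, _["in_ring"] = bring));
}

// Unique SMARTS matches; each element is the vector of (1-based) molecule
// atom indices in pattern-atom order.
// [[Rcpp::export(name = ".ob_match")]]
List ob_match(std::string smiles, std::string smarts, bool addh) {
  OBMol mol;
  if (!read_smiles(mol, smiles)) stop("unparseable SMILES: %s", smiles);
  if (addh) mol.AddHydrogens();
  OBSmartsPattern pat;
  if (!pat.Init(smarts)) stop("unparseable SMARTS: %s", smarts);
  pat.Match(mol);
  std::vector<std::vector<int> > maps = pat.GetUMapList();
  List out(maps.size());
  for (size_t k = 0; k < maps.size(); ++k) out[k] = wrap(maps[k]);
  return out;
}

// Any-match screen of molecules (rows) against patterns (columns).
// Patterns are compiled once; molecules with explicit hydrogens when addh,
// so patterns written with explicit [#1] atoms (e.g. PAINS) behave as
// published. Unparseable SMILES yield NA rows.
// [[Rcpp::export(name = ".ob_screen")]]
LogicalMatrix ob_screen(CharacterVector smiles, CharacterVector smarts,
                        bool addh) {
  const R_xlen_t n = smiles.size(), p = smarts.size();
  std::vector<OBSmartsPattern *> pats(p);
  for (R_xlen_t j = 0; j < p; ++j) {
    pats[j] = new OBSmartsPattern();
    if (!pats[j]->Init(as<std::string>(smarts[j]))) {
      for (R_xlen_t k = 0; k <= j; ++k) delete pats[k];
      stop("unparseable SMARTS: %s", as<std::string>(smarts[j]));
    }
  }
  LogicalMatrix out(n, p);
  for (R_xlen_t i = 0; i < n; ++i) {
    OBMol mol;
    if (!read_smiles(mol, as<std::string>(smiles[i]))) {
      for (R_xlen_t j = 0; j < p; ++j) out(i, j) = NA_LOGICAL;
      continue;
    }
    if (addh) mol.AddHydrogens();
    for (R_xlen_t j = 0; j < p; ++j)
      out(i, j) = pats[j]->Match(mol, true);
  }
  for (R_xlen_t j = 0; j < p; ++j) delete pats[j];
  return out;
}

// Physicochemical descriptor block. HBA/HBD use the Lipinski N+O convention;
// logP is Open Babel's Wildman-Crippen atom-contribution model.
// [[Rcpp::export(name = ".ob_descriptors")]]
DataFrame ob_descriptors(CharacterVector smiles) {
  const R_xlen_t n = smiles.size();
  NumericVector mw(n), logp(n), tpsa(n), fsp3(n);
  IntegerVector hba(n), hbd(n), rotb(n), hac(n), nrings_arom(n);
  LogicalVector ok(n);
  OBDescriptor *dlogp = OBDescriptor::FindType("logP");
  OBDescriptor *dtpsa = OBDescriptor::FindType("TPSA");
  if (!dlogp || !dtpsa) stop("Open Babel logP/TPSA descriptors unavailable");
  for (R_xlen_t i = 0; i < n; ++i) {
    OBMol mol;
    if (!read_smiles(mol, as<std::string>(smiles[i]))) {
      ok[i] = false;
      mw[i] = logp[i] = tpsa[i] = fsp3[i] = NA_REAL;
      hba[i] = hbd[i] = rotb[i] = hac[i] = nrings_arom[i] = NA_INTEGER;
      continue;
    }
    ok[i] = true;
    mw[i] = mol.GetMolWt();
    logp[i] = dlogp->Predict(&mol);
    tpsa[i] = dtpsa->Predict(&mol);
    rotb[i] = mol.NumRotors();
    hac[i] = mol.NumHvyAtoms();
    int acc = 0, don = 0, c_all = 0, c_sp3 = 0;
    FOR_ATOMS_OF_MOL(a, mol) {
      const int az = a->GetAtomicNum();
      if (az == 7 || az == 8) {
        ++acc;
        if (a->ExplicitHydrogenCount() + a->GetImplicitHCount() > 0) ++don;
      }
      if (az == 6) {
        ++c_all;
        bool sp3 = !a->IsAromatic();
        if (sp3) {
          FOR_BONDS_OF_ATOM(b, *a)
            if (b->GetBondOrder() > 1) { sp3 = false; break; }
        }
        if (sp3) ++c_sp3;
      }
    }
    hba[i] = acc;
    hbd[i] = don;
    fsp3[i] = c_all > 0 ? (double)c_sp3 / c_all : 0.0;
    int na = 0;
    std::vector<OBRing *> rings = mol.GetSSSR();
    for (size_t r = 0; r < rings.size(); ++r)
      if (rings[r]->IsAromatic()) ++na;
    nrings_arom[i] = na;
  }
  return DataFrame::create(
    _["ok"] = ok, _["mw"] = mw, _["clogp"] = logp, _["hba"] = hba,
    _["hbd"] = hbd, _["rotb"] = rotb, _["tpsa"] = tpsa, _["hac"] = hac,
    _["fsp3"] = fsp3, _["arom_rings"] = nrings_arom,
    _["stringsAsFactors"] = false);
}

// Distance-geometry style single-conformer build (OBBuilder) plus a short
// force-field relaxation; deterministic for a given input SMILES.
// [[Rcpp::export(name = ".ob_embed3d")]]
List ob_embed3d(std::string smiles, int steps) {
  OBMol mol;
  if (!read_smiles(mol, smiles)) return List::create(_["ok"] = false);
  mol.AddHydrogens();
  OBBuilder builder;
  if (!builder.Build(mol)) return List::create(_["ok"] = false);
  if (steps > 0) {
    OBForceField *ff = OBForceField::FindForceField("MMFF94");
    if (!ff || !ff->Setup(mol)) ff = OBForceField::FindForceField("UFF");
    if (ff && ff->Setup(mol)) {
      ff->SteepestDescent(steps);
      ff->GetCoordinates(mol);
    }
  }
  const int n = mol.NumAtoms();
  NumericMatrix xyz(n, 3);
  NumericVector mass(n);
  int i = 0;
  FOR_ATOMS_OF_MOL(a, mol) {
    xyz(i, 0) = a->GetX();
    xyz(i, 1) = a->GetY();
    xyz(i, 2) = a->GetZ();
    mass[i] = a->GetAtomicMass();
    ++i;
  }
  return List::create(_["ok"] = true, _["xyz"] = xyz, _["mass"] = mass);
}

// Largest connected fragment by heavy-atom count (salt stripping); ties go
// to the lexicographically smallest canonical SMILES.
// [[Rcpp::export(name = ".ob_largest_fragment")]]
CharacterVector ob_largest_fragment(CharacterVector smiles) {
  CharacterVector out(smiles.size());
  for (R_xlen_t i = 0; i < smiles.size(); ++i) {
    OBMol mol;
    if (!read_smiles(mol, as<std::string>(smiles[i]))) { out[i] = ""; continue; }
    std::vector<OBMol> frags = mol.Separate();
    if (frags.size() <= 1) { out[i] = write_format(mol, "can"); continue; }
    std::string best;
    unsigned best_hac = 0;
    for (size_t f = 0; f < frags.size(); ++f) {
      unsigned hac = frags[f].NumHvyAtoms();
      std::string smi = write_format(frags[f], "can");
      if (hac > best_hac || (hac == best_hac && (best.empty() || smi < best))) {
        best_hac = hac;
        best = smi;
      }
    }
    out[i] = best;
  }
  return out;
}

// [[Rcpp::export(name = ".ob_num_fragments")]]
IntegerVector ob_num_fragments(CharacterVector smiles) {
  IntegerVector out(smiles.size());
  for (R_xlen_t i = 0; i < smiles.size(); ++i) {
    OBMol mol;
    if (!read_smiles(mol, as<std::string>(smiles[i]))) { out[i] = NA_INTEGER; continue; }
    out[i] = (int)mol.Separate().size();
  }
  return out;
}
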