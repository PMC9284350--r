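keyword,variant
Acebutolol,N/A
Atenolol,Atenelol
Atenolol,atenonol
Atenolol,atenanol
Atenolol,antenolol
Atenolol,atenol
Atenolol,atenolo
Atenolol,atenalol
Atenolol,antenenol
Atenolol,atentol
Atenolol,atenenol
Atenolol,attenalol
Atenolol,atenlol
Atenolol,attenolol
Atenolol,altenolol
Beta blocker,Beta-blocker
Beta blocker,b blocker
Beta blocker,b-blocker
Beta blocker,beta blockers
Beta blocker,beta-blockers
Beta blocker,b blockers
Beta blocker,b-blockers
Beta blocker,betablocker
Beta blocker,bblocker
Beta blocker,betablockers
Beta blocker,bblockers
Carvedilol,Carvidolol
Coreg,N/A
Corgard,N/A
Inderal,Inderall
Inderal,inderol
Labetalol,Labetolol
Lopressor,N/A
Metoprolol,Metopolol
Metoprolol,metropolol
Metoprolol,metorolol
Metoprolol,metroprolol
Metoprolol,metaprolol
Metoprolol,metoporol
Metoprolol,metprolol
Metoprolol,metotoprolol
Metoprolol,metropolo
Metoprolol,metroplol
Metoprolol,meteprolol
Metoprolol,metoprol
Metoprolol,metroporol
Metoprolol,metoprolo
Nadolol,Nadalol
Normodyne,N/A
Propranolol,Propananol
Propranolol,propanonol
Propranolol,proprapanol
Propranolol,propranonol
Propranolol,proranolol
Propranolol,propanolol
Propranolol,propranalol
Propranolol,proprananol
Propranolol,propanalol
Propranolol,propronolol
Sectral,N/A
Trandate,N/A
Tenormin,N/A
Toprol,Toprol
Toprol,toprolol
Toprol,topral
Toprol,toperol
Toprol,tropol
Toprol,toporal
Toprol,toporol
Toprol,toporolol
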